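# shared small scene configurations; cached so several test files can use
# the same rendered scene without regenerating it

.scene_cache <- new.env(parent = emptyenv())

test_scene <- function(key = "default", ...) {
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- generate_scene(test_scene_config(...))
  .scene_cache[[key]] <- sc
  sc
}

test_scene_config <- function(...) {
  args <- list(...)
  base <- list(image_size_px = c(448L, 448L), n_ais = 5L,
               ais_length_um = 10, ais_puncta_density_per_100um2 = 30,
               nonais_puncta_density_per_100um2 = 10, seed = 11L)
  base[names(args)] <- args
  do.call(scene_config, base)
}

# quiet wrapper for the quantification configs used in several files
quant_config <- function(cfg, ...) {
  modifyList(list(scene = cfg, channel = cfg$subunit_label,
                  preprocess = list(rolling_ball_radius_px = 12)),
             list(...))
}
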