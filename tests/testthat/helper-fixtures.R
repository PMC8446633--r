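# Shared fixtures: synthetic scenes and (expensively) trained models are
# built once per test run and memoised in this environment.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# the study conditions: default scene spec, varying only the seed
study_scene <- function(seed) generate_scene(scene_spec(seed = seed))

study_scenes <- function(seeds) {
  memo(paste0("scenes_", min(seeds), "_", max(seeds)),
       lapply(seeds, study_scene))
}

# 40 training + 10 held-out scenes used by the scaled-down learning checks
train_scenes <- function() study_scenes(1:40)
heldout_scenes <- function() study_scenes(101:110)

seg_pairs <- function(scenes) {
  lapply(scenes, function(s) list(image = s$micrograph, mask = s$truth$wall_mask))
}

det_records <- function(scenes) {
  lapply(scenes, function(s) list(micrograph = s$micrograph,
                                  boxes = s$truth$stoma_boxes))
}

# desk-scale segmenter: 40 pairs, 15 epochs (trained once per run); the
# initial rate is larger than the full 200-epoch protocol's because the
# desk run takes two orders of magnitude fewer optimizer steps
desk_seg_config <- function(seed = 421, epochs = 15) {
  seg_config(input_size = c(256, 256), batch_size = 1,
             lr_initial = 3e-4, lr_final = 3e-5, epochs = epochs,
             depth = 3, width = 8, seed = seed)
}

trained_segmenter <- function() {
  memo("segmenter", train_segmenter(seg_pairs(train_scenes()), desk_seg_config()))
}

# desk-scale detector on the same scenes
trained_detector <- function() {
  memo("detector", {
    cfg <- detector_config(input_size = c(256, 256), widths = c(8, 16, 32),
                           batch_size = 4, lr_initial = 5e-4, lr_final = 5e-5,
                           epochs = 40, n_sample = 256, seed = 422)
    train_detector(det_records(train_scenes()), cfg)
  })
}

# small segmenter trained on a 10-scene seed subset (semi-automatic loop)
seed_subset_segmenter <- function() {
  memo("segmenter10", {
    cfg <- desk_seg_config(seed = 423, epochs = 12)
    cfg$batch_size <- 1L
    train_segmenter(seg_pairs(study_scenes(201:210)), cfg)
  })
}
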