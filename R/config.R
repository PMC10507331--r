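# ---------------------------------------------------------------------------
# Configuration. Two built-in profiles:
#   "paper" — the full-scale architecture (550x550 input, 256-channel
#             pyramid, 32 prototypes, SGD lr 0.001 / batch 16 / 600 epochs).
#   "desk"  — a width-reduced profile for CPU-scale runs and the test suite
#             (128x128 input, 1/8-width backbone with one bottleneck per
#             stage, 32-channel pyramid, 8 prototypes).
# ---------------------------------------------------------------------------

#' Default detector configuration
#'
#' @param profile `"paper"` (full scale) or `"desk"` (reduced, CPU scale)
#' @return nested configuration list
#' @export
default_config <- function(profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    input_size = 550L,
    backbone = list(arch = "ghost_resnet50", S = 4L, cheap_kernel = 3L,
                    replace_stem = FALSE, width_mult = 1,
                    stage_blocks = c(3L, 4L, 6L, 3L)),
    neck = list(type = "dffn", channels = 256L),
    attention = list(kind = "fcam_sam", r = 16L,
                     components = list(c(0L, 0L), c(0L, 1L), c(1L, 0L))),
    heads = list(k = 32L, n_classes = 1L, aspects = c(1, 0.5, 2),
                 scales = c(24, 48, 96, 192, 384), tower_convs = 1L,
                 proto_convs = 3L),
    train = list(optimizer = "sgd", learning_rate = 0.001, batch_size = 16L,
                 epochs = 600L, momentum = 0.9, weight_decay = 5e-4,
                 seed = 42L, augment = TRUE, ohem_ratio = 3, grad_clip = 5,
                 loss_weights = c(cls = 1, box = 1.5, mask = 6.125),
                 pos_thr = 0.5, neg_thr = 0.4),
    predict = list(score_thr = 0.05, nms_iou = 0.5, top_k = 200L,
                   mask_threshold = 0.5, crop_pad = 0),
    normalize = list(mean = 0.5, sd = 0.25)
  )
  if (profile == "desk") {
    cfg$input_size <- 128L
    cfg$backbone$width_mult <- 0.125
    cfg$backbone$stage_blocks <- c(1L, 1L, 1L, 1L)
    cfg$neck$channels <- 32L
    cfg$attention$r <- 4L
    cfg$heads$k <- 8L
    cfg$heads$scales <- c(16, 32, 56, 88, 120)
    cfg$heads$proto_convs <- 2L
    cfg$train$learning_rate <- 0.02
    cfg$train$batch_size <- 4L
    cfg$train$epochs <- 30L
  }
  cfg
}

#' Recursively merge configuration overrides into a base configuration
#'
#' @param base base list
#' @param override named list of overrides (nested lists merge recursively)
#' @return merged list
#' @export
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a configuration from a YAML file, merged over a profile default
#'
#' The YAML may set `profile: desk` to start from the reduced profile.
#' @param path YAML file path
#' @return configuration list
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- if (!is.null(y$profile)) y$profile else "paper"
  merge_config(default_config(profile), y)
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
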