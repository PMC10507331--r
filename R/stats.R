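# ---------------------------------------------------------------------------
# Exact parameter counting and analytic multiply-add (FLOP) counting.
# ---------------------------------------------------------------------------

#' Count trainable parameters of a model
#'
#' Sums the element counts of every trainable array (convolution and linear
#' weights, biases, and the affine scale/shift of each normalization layer).
#' Running statistics are buffers, not parameters, and are excluded.
#'
#' @param model any module built by this package (backbone, neck, detector, ...)
#' @return exact integer count (as a double to avoid 32-bit overflow)
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model_layers(model))
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

# accept either a raw module/layer or a container with $layers
model_layers <- function(model) {
  if (inherits(model, "wbc_layer")) return(model)
  if (!is.null(model$layers)) return(model$layers)
  model
}

#' Per-layer parameter table
#'
#' @inheritParams count_parameters
#' @return data.frame with one row per parameter array
#' @export
parameter_table <- function(model) {
  ps <- collect_params(model_layers(model))
  data.frame(name = names(ps),
             count = vapply(ps, function(p) length(p$value), numeric(1)),
             row.names = NULL)
}

#' Analytic multiply-add count
#'
#' Runs a shape-trace forward pass on a zero image and accumulates one
#' multiply-add per convolution/linear inner-product term
#' (`k^2 * C_in * C_out * H_out * W_out / groups` per convolution). Channel
#' normalization, activations and pooling are excluded; a multiply-add counts
#' as one FLOP, the convention under which standard ResNet-50 at 550x550
#' lands near the 25.66 G reported for that architecture.
#'
#' @param model a backbone from [build_backbone()] or detector from
#'   [build_detector()]
#' @param input_size input image side length in pixels (square input)
#' @return multiply-add count (double)
#' @export
count_flops <- function(model, input_size = 550L) {
  ctr <- new.env(parent = emptyenv())
  ctr$macs <- 0
  .wbc$flop_counter <- ctr
  on.exit(.wbc$flop_counter <- NULL)
  img <- array(0, dim = c(input_size, input_size, 3L))
  if (inherits(model, "wbc_backbone")) {
    if (model$meta$include_classifier) {
      model$forward_classifier(tn_const(img), train = FALSE)
    } else {
      model$forward_features(tn_const(img), train = FALSE)
    }
  } else if (inherits(model, "wbc_detector")) {
    detector_forward(model, img, train = FALSE)
  } else stop("unsupported model type")
  ctr$macs
}

#' Architecture statistics
#'
#' @inheritParams count_flops
#' @param with_flops also run the analytic FLOP trace (slower)
#' @return a `wbc_model_stats` list: exact `params`, `params_m` (millions,
#'   2 d.p.), optional `flops`/`flops_g`, and the per-layer table
#' @export
model_stats <- function(model, input_size = 550L, with_flops = FALSE) {
  tab <- parameter_table(model)
  params <- sum(tab$count)
  out <- list(params = params, params_m = round(params / 1e6, 2),
              layer_table = tab)
  if (with_flops) {
    out$flops <- count_flops(model, input_size)
    out$flops_g <- round(out$flops / 1e9, 2)
    out$input_size <- input_size
  }
  structure(out, class = "wbc_model_stats")
}

#' @export
print.wbc_model_stats <- function(x, ...) {
  cat(sprintf("params: %s (%.2f M)\n", format(x$params, big.mark = ","),
              x$params_m))
  if (!is.null(x$flops))
    cat(sprintf("flops:  %s MACs (%.2f G) at %d px\n",
                format(x$flops, big.mark = ","), x$flops_g, x$input_size))
  cat(sprintf("layers: %d parameter arrays\n", nrow(x$layer_table)))
  invisible(x)
}

# Build large models with zero-filled weights (skips RNG work) when only
# counting; forward passes through such a model are still well-defined.
with_zero_init <- function(expr) {
  old <- .wbc$zero_init
  .wbc$zero_init <- TRUE
  on.exit(.wbc$zero_init <- old)
  expr
}
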