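#' BioUMixer architecture configuration
#'
#' All structural hyperparameters of the network live here. The `"tiny"`
#' preset (64x64 input, stage widths 32/64/128, one block per kind per
#' stage) is sized for CPU-scale experiments and the synthetic canopy
#' scenes; the `"standard"` preset targets 224x224 field imagery.
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `patch_size` times the cumulative downsampling factor.
#' @param patch_size patch-embedding patch side in pixels.
#' @param stage_widths integer vector of channel widths, one per stage.
#'   Spatial resolution halves between consecutive stages.
#' @param blocks_per_stage number of FeatureBlock/BioBlock pairs per stage.
#' @param embedding_dim dimension of the image embedding `v` consumed by
#'   the contrastive loss.
#' @param drop_path_rate stochastic-depth rate in `[0, 1)` applied to
#'   residual branches during training.
#' @param simam_lambda positive regularizer of the SimAM energy.
#' @param mixer_token_hidden,mixer_channel_hidden hidden sizes of the
#'   token-mixing and channel-mixing MLPs in the head.
#' @param head_hidden hidden width of the final prediction MLP.
#' @param skip_projection `"conv1x1"` (project skip channels, default) or
#'   `"identity"` (only legal when widths match).
#' @param preset `"tiny"` or `"standard"`; explicit arguments override
#'   preset values.
#' @return An object of class `bioumixer_config`.
#' @export
bioumixer_config <- function(preset = c("tiny", "standard"),
                             input_size = NULL, patch_size = 4L,
                             stage_widths = c(32L, 64L, 128L),
                             blocks_per_stage = NULL,
                             embedding_dim = 128L,
                             drop_path_rate = 0,
                             simam_lambda = 1e-4,
                             mixer_token_hidden = 64L,
                             mixer_channel_hidden = 256L,
                             head_hidden = 64L,
                             skip_projection = c("conv1x1", "identity")) {
  preset <- match.arg(preset)
  skip_projection <- match.arg(skip_projection)
  if (is.null(input_size)) input_size <- if (preset == "tiny") 64L else 224L
  if (is.null(blocks_per_stage)) {
    blocks_per_stage <- if (preset == "tiny") rep(1L, length(stage_widths))
                        else rep(2L, length(stage_widths))
  }
  if (length(blocks_per_stage) == 1L) {
    blocks_per_stage <- rep(as.integer(blocks_per_stage), length(stage_widths))
  }
  if (length(blocks_per_stage) != length(stage_widths)) {
    stop_config("`blocks_per_stage` must match `stage_widths` in length")
  }
  if (any(stage_widths <= 0) || any(blocks_per_stage <= 0)) {
    stop_config("stage widths and block counts must be positive")
  }
  check_number(patch_size, "patch_size", lower = 1)
  check_number(drop_path_rate, "drop_path_rate", lower = 0, upper = 1 - 1e-9)
  check_number(simam_lambda, "simam_lambda", lower = 0, strict_lower = TRUE)
  n_stages <- length(stage_widths)
  down_factor <- patch_size * 2^(n_stages - 1L)
  if (input_size %% down_factor != 0) {
    stop_config(sprintf(
      "`input_size` (%d) must be divisible by patch_size * 2^(n_stages-1) = %d",
      input_size, down_factor))
  }
  final_side <- input_size %/% down_factor
  if (final_side < 2) {
    stop_config("final feature map is smaller than 2x2; enlarge `input_size`")
  }
  structure(list(
    preset = preset,
    input_size = as.integer(input_size),
    patch_size = as.integer(patch_size),
    stage_widths = as.integer(stage_widths),
    blocks_per_stage = as.integer(blocks_per_stage),
    embedding_dim = as.integer(embedding_dim),
    drop_path_rate = drop_path_rate,
    simam_lambda = simam_lambda,
    mixer_token_hidden = as.integer(mixer_token_hidden),
    mixer_channel_hidden = as.integer(mixer_channel_hidden),
    head_hidden = as.integer(head_hidden),
    skip_projection = skip_projection
  ), class = "bioumixer_config")
}

#' @export
print.bioumixer_config <- function(x, ...) {
  cat(sprintf("BioUMixer config (%s): input %dx%d, patch %d, widths [%s], blocks [%s], d_emb %d\n",
              x$preset, x$input_size, x$input_size, x$patch_size,
              paste(x$stage_widths, collapse = ", "),
              paste(x$blocks_per_stage, collapse = ", "),
              x$embedding_dim))
  invisible(x)
}

default_toggles <- function(toggles = NULL) {
  full <- list(skips = TRUE, feature_block = TRUE, bio_block = TRUE)
  if (is.null(toggles)) return(full)
  unknown <- setdiff(names(toggles), names(full))
  if (length(unknown)) {
    stop_config(paste0("unknown ablation toggles: ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(full, lapply(toggles, isTRUE))
}
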