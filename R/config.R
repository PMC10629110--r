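#' Network, loss and training configuration
#'
#' Builds the full hyperparameter set for the multi-task network: encoder
#' widths, multi-scale-attention branch kernels, transformer head geometry,
#' focal/Dice loss constants, task-weighting mode and optimizer settings.
#' Defaults follow the published operating point: input side 384, branch
#' kernels 5/7/11, focal alpha 0.8 and gamma 2, focal scale beta = 1/25000,
#' learning rate 3e-4, early-stopping patience 20 epochs, and uncertainty
#' task weighting with both sigmas initialized at 1.
#'
#' @param input_size square input side in pixels; must be divisible by 16.
#' @param stage_channels integer vector of 5 encoder widths, one per
#'   resolution level (full resolution down to 1/16).
#' @param branch_kernels three odd strip-convolution kernel sizes for the
#'   multi-scale attention branches.
#' @param shared_dw_kernel odd kernel side of the shared depth-wise
#'   convolution feeding the branches.
#' @param num_heads attention heads; must divide the deepest channel count.
#' @param patch_grid the deepest feature map is split into
#'   \code{patch_grid^2} patches; must divide \code{input_size/16}.
#' @param pool_kernel kernel (= stride) of the average pooling after the
#'   transformer block; must divide \code{input_size/16}.
#' @param mlp_hidden hidden width of the classifier MLP head.
#' @param ffn_mult feed-forward expansion factor inside the transformer block.
#' @param focal_alpha foreground balance weight of the focal loss, in (0,1).
#' @param focal_gamma focusing exponent of the focal loss, >= 0.
#' @param focal_scale_beta scale applied to the (pixel-summed) focal loss
#'   before adding it to the Dice loss.
#' @param weighting_mode \code{"uncertainty"} for learned homoscedastic task
#'   weights, \code{"equal"} for fixed 0.5/0.5 weights.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param dice_epsilon smoothing constant of the Dice loss denominator.
#' @param seed integer seed used for weight initialization and shuffling.
#' @param seg_threshold probability threshold binarizing segmentation maps.
#' @param class_threshold patient-level mutation call threshold; the call is
#'   mutant only when the mean probability strictly exceeds it.
#' @param batch_size training minibatch size (slices).
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param min_delta minimal validation-loss improvement that resets patience.
#' @param downsample \code{"conv"} (stride-2 3x3 convolution) or
#'   \code{"maxpool"}.
#' @param prob_floor probability floor applied before any logarithm.
#' @return a validated object of class \code{mtsa_config}.
#' @seealso [validate_config()], [read_config()], [write_config()]
#' @export
mtsa_config <- function(input_size = 384L,
                        stage_channels = c(32L, 64L, 128L, 256L, 512L),
                        branch_kernels = c(5L, 7L, 11L),
                        shared_dw_kernel = 5L,
                        num_heads = 8L,
                        patch_grid = 4L,
                        pool_kernel = 4L,
                        mlp_hidden = 256L,
                        ffn_mult = 4L,
                        focal_alpha = 0.8,
                        focal_gamma = 2,
                        focal_scale_beta = 1 / 25000,
                        weighting_mode = "uncertainty",
                        learning_rate = 3e-4,
                        patience = 20L,
                        dice_epsilon = 1e-6,
                        seed = 0L,
                        seg_threshold = 0.5,
                        class_threshold = 0.5,
                        batch_size = 8L,
                        bn_momentum = 0.1,
                        min_delta = 1e-6,
                        downsample = "conv",
                        prob_floor = 1e-7) {
  cfg <- list(
    input_size = as.integer(input_size),
    stage_channels = as.integer(stage_channels),
    branch_kernels = as.integer(branch_kernels),
    shared_dw_kernel = as.integer(shared_dw_kernel),
    num_heads = as.integer(num_heads),
    patch_grid = as.integer(patch_grid),
    pool_kernel = as.integer(pool_kernel),
    mlp_hidden = as.integer(mlp_hidden),
    ffn_mult = as.integer(ffn_mult),
    focal_alpha = as.numeric(focal_alpha),
    focal_gamma = as.numeric(focal_gamma),
    focal_scale_beta = as.numeric(focal_scale_beta),
    weighting_mode = as.character(weighting_mode),
    learning_rate = as.numeric(learning_rate),
    patience = as.integer(patience),
    dice_epsilon = as.numeric(dice_epsilon),
    seed = as.integer(seed),
    seg_threshold = as.numeric(seg_threshold),
    class_threshold = as.numeric(class_threshold),
    batch_size = as.integer(batch_size),
    bn_momentum = as.numeric(bn_momentum),
    min_delta = as.numeric(min_delta),
    downsample = as.character(downsample),
    prob_floor = as.numeric(prob_floor)
  )
  class(cfg) <- "mtsa_config"
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks every structural invariant of an [mtsa_config()] object and returns
#' it unchanged when all hold; otherwise stops with a message naming the
#' violated invariant. Idempotent.
#'
#' @param cfg an \code{mtsa_config} object.
#' @return \code{cfg}, unchanged.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "mtsa_config")) stop("not an mtsa_config object")
  if (cfg$input_size %% 16L != 0L)
    stop("input_size not divisible by 16 (got ", cfg$input_size, ")")
  if (length(cfg$stage_channels) != 5L)
    stop("stage_channels must have 5 entries (got ",
         length(cfg$stage_channels), ")")
  if (any(cfg$stage_channels < 1L)) stop("stage_channels must be positive")
  deepest <- cfg$stage_channels[5L]
  if (deepest %% cfg$num_heads != 0L)
    stop("channels not divisible by heads (deepest ", deepest,
         ", heads ", cfg$num_heads, ")")
  side16 <- cfg$input_size %/% 16L
  if (side16 %% cfg$patch_grid != 0L)
    stop("input_size/16 (= ", side16, ") not divisible by patch_grid (",
         cfg$patch_grid, ")")
  if (side16 %% cfg$pool_kernel != 0L)
    stop("input_size/16 (= ", side16, ") not divisible by pool_kernel (",
         cfg$pool_kernel, ")")
  if (any(cfg$branch_kernels %% 2L == 0L))
    stop("branch kernels must be odd (got ",
         paste(cfg$branch_kernels, collapse = ","), ")")
  if (cfg$shared_dw_kernel %% 2L == 0L) stop("shared_dw_kernel must be odd")
  if (!(cfg$focal_alpha > 0 && cfg$focal_alpha < 1))
    stop("focal_alpha must lie in (0,1)")
  if (cfg$focal_gamma < 0) stop("focal_gamma must be >= 0")
  if (cfg$dice_epsilon <= 0) stop("dice_epsilon must be > 0")
  if (!cfg$weighting_mode %in% c("uncertainty", "equal"))
    stop("weighting_mode must be 'uncertainty' or 'equal'")
  if (!cfg$downsample %in% c("conv", "maxpool"))
    stop("downsample must be 'conv' or 'maxpool'")
  if (cfg$patience < 1L) stop("patience must be >= 1")
  if (cfg$seg_threshold < 0 || cfg$seg_threshold > 1)
    stop("seg_threshold must lie in [0,1]")
  if (cfg$class_threshold < 0 || cfg$class_threshold > 1)
    stop("class_threshold must lie in [0,1]")
  cfg
}

#' Write a configuration to a YAML file
#' @param cfg an \code{mtsa_config} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Field names mirror the arguments of [mtsa_config()]; reading a file
#' written by [write_config()] reproduces an equal configuration.
#'
#' @param path YAML file path.
#' @return a validated \code{mtsa_config} object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(mtsa_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(mtsa_config, raw)
}

#' @export
print.mtsa_config <- function(x, ...) {
  cat("Multi-task network configuration\n")
  cat(sprintf("  input %dx%d, encoder channels [%s]\n", x$input_size,
              x$input_size, paste(x$stage_channels, collapse = ", ")))
  cat(sprintf("  MSA branches k = %s (shared depth-wise %dx%d)\n",
              paste(x$branch_kernels, collapse = "/"),
              x$shared_dw_kernel, x$shared_dw_kernel))
  cat(sprintf("  classifier: %d heads, %dx%d patches, pool %d, MLP hidden %d\n",
              x$num_heads, x$patch_grid, x$patch_grid, x$pool_kernel,
              x$mlp_hidden))
  cat(sprintf("  loss: alpha %.2f gamma %.1f beta %.2e, weighting '%s'\n",
              x$focal_alpha, x$focal_gamma, x$focal_scale_beta,
              x$weighting_mode))
  cat(sprintf("  training: lr %.1e, batch %d, patience %d, seed %d\n",
              x$learning_rate, x$batch_size, x$patience, x$seed))
  invisible(x)
}
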