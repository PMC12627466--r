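# Model configuration and the parameter shape plan.
#
# Every learnable array in the network is declared once, by name and
# dimension, in fthnet_shapes(). Initialisation, parameter counting and the
# forward/backward passes all consume this single shape plan, so the
# calibration harness counts exactly what the model trains.

#' Model configuration
#'
#' @param depths integer(4), number of transformer blocks per stage
#'   (N1..N4).
#' @param embed_channels patch-embedding width C; stage i (i = 0..3) runs at
#'   spatial side `input_size / (4 * 2^i)` with `2^i * C` channels.
#' @param input_size training resolution (square). Must be divisible by 32
#'   and by `32 * window` so that all stage sides are window-divisible.
#' @param window attention window side; defaults to `input_size / 32`, the
#'   only choice that divides every stage side (12 at 384).
#' @param mlp_ratio hidden expansion of the per-block MLP.
#' @param head_scheme how per-stage head counts are derived: `"scaled"`
#'   (heads_i = 2^i * max(2, C %/% 32), the calibrated default), `"dim32"`
#'   or `"dim16"` (channels / 32 or / 16, minimum 1).
#' @param rel_pos_bias include a learned relative position bias per window.
#' @param semantic_len per-stage distortion vector length l; the semantic
#'   vector has length L = 4 l (L must be divisible by 16).
#' @param hyper_width internal channel width of the hypernetwork's first
#'   stage (halved at each of its five stages). The deepest backbone
#'   feature is merged to this width by a 1x1 convolution.
#' @param hypernet if `FALSE`, the scoring head is a learned static
#'   five-layer MLP instead of hypernetwork-generated (ablation).
#' @param downsample_kernel side of the stride-2 downsampling convolution
#'   between stages (2, the calibrated default, or 4).
#' @param drop dropout rate of MLP layers (kept 0; evaluation and training
#'   are deterministic).
#' @return object of class `fthnet_config`.
#' @export
model_config <- function(depths = c(2, 2, 6, 2), embed_channels = 64,
                         input_size = 384L, window = input_size %/% 32L,
                         mlp_ratio = 4, head_scheme = c("scaled", "dim32", "dim16"),
                         rel_pos_bias = TRUE, semantic_len = 156L,
                         hyper_width = 160L, hypernet = TRUE,
                         downsample_kernel = 2L, drop = 0) {
  head_scheme <- match.arg(head_scheme)
  depths <- as.integer(depths)
  C <- as.integer(embed_channels)
  S <- as.integer(input_size)
  w <- as.integer(window)
  if (length(depths) != 4L || any(depths < 1L))
    stop("model_config: depths must be four integers >= 1")
  if (C %% 2L) stop("model_config: embed_channels must be even")
  if (S %% 32L) stop("model_config: input_size must be divisible by 32")
  for (i in 0:3) {
    side <- S %/% (4L * 2L^i)
    if (side %% w)
      stop("model_config: window ", w, " does not divide stage ", i,
           " side ", side)
  }
  L <- 4L * as.integer(semantic_len)
  if (L %% 16L) stop("model_config: 4 * semantic_len must be divisible by 16")
  if (as.integer(hyper_width) %% 16L)
    stop("model_config: hyper_width must be divisible by 16")
  structure(list(depths = depths, embed_channels = C, input_size = S,
                 window = w, mlp_ratio = mlp_ratio, head_scheme = head_scheme,
                 rel_pos_bias = isTRUE(rel_pos_bias),
                 semantic_len = as.integer(semantic_len),
                 hyper_width = as.integer(hyper_width),
                 hypernet = isTRUE(hypernet),
                 downsample_kernel = as.integer(downsample_kernel),
                 drop = drop),
            class = "fthnet_config")
}

#' @export
print.fthnet_config <- function(x, ...) {
  cat(sprintf("fthnet config: depths (%s), C=%d, input %d, window %d, l=%d, hyper width %d%s\n",
              paste(x$depths, collapse = ","), x$embed_channels, x$input_size,
              x$window, x$semantic_len, x$hyper_width,
              if (x$hypernet) "" else " [static head]"))
  cat(sprintf("  parameters: %.3f M\n", count_parameters(x) / 1e6))
  invisible(x)
}

stage_channels <- function(config, i) config$embed_channels * 2L^(i - 1L)
stage_side <- function(config, i) config$input_size %/% (4L * 2L^(i - 1L))

stage_heads <- function(config, i) {
  C <- config$embed_channels
  D <- stage_channels(config, i)
  switch(config$head_scheme,
         scaled = 2L^(i - 1L) * max(2L, C %/% 32L),
         dim32 = max(1L, D %/% 32L),
         dim16 = max(1L, D %/% 16L))
}

#' Named model presets
#'
#' `fthnet_s()` and `fthnet_l()` are the small and large reference models
#' (depths (2,4,6,2) C=32 and (2,2,6,2) C=64 at 384 input). `fthnet_tiny()`
#' is a CPU desk preset: depths (1,1,1,1), C=16, l=32, 192-pixel input
#' (window 6) - the same architecture family at a quarter of the pixels,
#' used by the package's training sanity checks.
#' @return an [model_config()].
#' @export
fthnet_s <- function() model_config(depths = c(2, 4, 6, 2), embed_channels = 32)

#' @rdname fthnet_s
#' @export
fthnet_l <- function() model_config(depths = c(2, 2, 6, 2), embed_channels = 64)

#' @rdname fthnet_s
#' @export
fthnet_tiny <- function() {
  model_config(depths = c(1, 1, 1, 1), embed_channels = 16, input_size = 192L,
               semantic_len = 32L, hyper_width = 64L)
}

#' Shape plan of the five generated target layers
#'
#' The scoring head halves its width at each of five linear layers:
#' (L -> L/2), (L/2 -> L/4), (L/4 -> L/8), (L/8 -> L/16), (L/16 -> 1).
#'
#' @param L semantic vector length, divisible by 16.
#' @return list of 5 elements, each `list(in_dim, out_dim)`.
#' @examples
#' plan_target_shapes(384)
#' @export
plan_target_shapes <- function(L) {
  L <- as.integer(L)
  if (L < 16L || L %% 16L)
    stop("plan_target_shapes: L must be a positive multiple of 16, got ", L)
  dims <- c(L, L %/% 2L, L %/% 4L, L %/% 8L, L %/% 16L, 1L)
  lapply(1:5, function(i) list(in_dim = dims[i], out_dim = dims[i + 1]))
}

# Complete shape plan: named list of dim vectors for every learnable array.
fthnet_shapes <- function(config) {
  C <- config$embed_channels; w <- config$window; r <- config$mlp_ratio
  sh <- list()
  sh[["embed.W"]] <- c(4 * 4 * 3, C); sh[["embed.b"]] <- C
  for (i in 1:4) {
    D <- stage_channels(config, i)
    h <- stage_heads(config, i)
    for (j in seq_len(config$depths[i])) {
      p <- sprintf("bb.s%d.b%d.", i, j)
      sh[[paste0(p, "ln1.g")]] <- D; sh[[paste0(p, "ln1.b")]] <- D
      sh[[paste0(p, "qkv.W")]] <- c(D, 3 * D); sh[[paste0(p, "qkv.b")]] <- 3 * D
      sh[[paste0(p, "proj.W")]] <- c(D, D); sh[[paste0(p, "proj.b")]] <- D
      if (config$rel_pos_bias)
        sh[[paste0(p, "rpb")]] <- c((2 * w - 1)^2, h)
      sh[[paste0(p, "ln2.g")]] <- D; sh[[paste0(p, "ln2.b")]] <- D
      sh[[paste0(p, "fc1.W")]] <- c(D, r * D); sh[[paste0(p, "fc1.b")]] <- r * D
      sh[[paste0(p, "fc2.W")]] <- c(r * D, D); sh[[paste0(p, "fc2.b")]] <- D
    }
    if (i < 4) {
      k <- config$downsample_kernel
      sh[[sprintf("bb.ds%d.W", i)]] <- c(k * k * D, 2 * D)
      sh[[sprintf("bb.ds%d.b", i)]] <- 2 * D
    }
  }
  l <- config$semantic_len
  kp <- config$input_size %/% 32L # SoftPool kernel: every stage pools to S/32/...
  for (i in 1:4) {
    D <- stage_channels(config, i)
    side <- stage_side(config, i)
    flat <- (side %/% kp)^2 * (D %/% 8L)
    p <- sprintf("dpb.s%d.", i)
    sh[[paste0(p, "conv.W")]] <- c(D, D %/% 8L); sh[[paste0(p, "conv.b")]] <- D %/% 8L
    sh[[paste0(p, "lin.W")]] <- c(flat, l); sh[[paste0(p, "lin.b")]] <- l
  }
  L <- 4L * l
  plan <- plan_target_shapes(L)
  if (config$hypernet) {
    m0 <- config$hyper_width
    A <- (config$input_size %/% 32L)^2
    sh[["hyp.in.W"]] <- c(8 * C, m0); sh[["hyp.in.b"]] <- m0
    for (i in 1:5) {
      m <- m0 %/% 2L^(i - 1L)
      if (i > 1) {
        sh[[sprintf("hyp.merge%d.W", i - 1L)]] <- c(2 * m, m)
        sh[[sprintf("hyp.merge%d.b", i - 1L)]] <- m
      }
      E <- plan[[i]]$in_dim * plan[[i]]$out_dim
      K <- ceiling(E / A)
      sh[[sprintf("hyp.pgl%d.wconv.W", i)]] <- c(3 * 3 * m, K)
      sh[[sprintf("hyp.pgl%d.wconv.b", i)]] <- K
      sh[[sprintf("hyp.pgl%d.blin.W", i)]] <- c(m, plan[[i]]$out_dim)
      sh[[sprintf("hyp.pgl%d.blin.b", i)]] <- plan[[i]]$out_dim
    }
  } else {
    for (i in 1:5) {
      sh[[sprintf("head%d.W", i)]] <- c(plan[[i]]$in_dim, plan[[i]]$out_dim)
      sh[[sprintf("head%d.b", i)]] <- plan[[i]]$out_dim
    }
  }
  sh
}

#' Count trainable parameters
#'
#' The count is the sum over the model's shape plan - the same plan that
#' allocates the arrays the optimiser updates. Generated target-network
#' weights are activations, not parameters, and are excluded (with
#' `hypernet = FALSE` the static head's parameters are included instead).
#' Pure function of the configuration; no RNG.
#'
#' @param config an [model_config()].
#' @return integer parameter count.
#' @examples
#' count_parameters(fthnet_l()) / 1e6
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "fthnet_config"))
  sum(vapply(fthnet_shapes(config), prod, 0))
}

#' Initialise model parameters
#'
#' Allocates every learnable array of the model's shape plan.
#' Transformer-block weights use the truncated normal sd 0.02 customary
#' for windowed-attention blocks (LayerNorm in front of every sublayer
#' makes blocks scale-invariant); all other weights (patch embedding,
#' downsampling, distortion blocks, hypernetwork) use fan-in scaling
#' (sd = 1/sqrt(fan_in)) so the unnormalised feature paths feeding the
#' hypernetwork preserve signal magnitude. Biases start at zero,
#' LayerNorm gains at one, and the bias of the last generated layer's
#' bias branch at 50 so that raw-score regression on the 0-100 scale
#' starts mid-scale.
#'
#' @param config an [model_config()].
#' @param seed integer seed (deterministic initialisation).
#' @return named list of parameter arrays.
#' @export
init_fthnet <- function(config, seed = 1L) {
  shapes <- fthnet_shapes(config)
  withr::with_seed(as.integer(seed), {
    params <- lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      if (grepl("\\.(g)$", nm)) return(rep(1, d))
      if (grepl("\\.(b)$", nm)) return(rep(0, d))
      if (grepl("rpb$", nm)) return(matrix(0, d[1], d[2]))
      sdev <- if (grepl("^bb\\.s", nm)) 0.02 else 1 / sqrt(d[1])
      v <- trunc_normal(prod(d), sd = sdev)
      if (length(d) > 1) matrix(v, d[1], d[2]) else v
    })
    names(params) <- names(shapes)
    if (config$hypernet) params[["hyp.pgl5.blin.b"]] <- 50
    if (!config$hypernet) params[["head5.b"]] <- 50
    params
  })
}

#' Read / write a model configuration as YAML
#'
#' The YAML file mirrors the [model_config()] fields one-to-one, so a
#' configuration can travel with a checkpoint or an experiment directory.
#'
#' @param path YAML file path.
#' @return `read_model_config()`: an [model_config()];
#'   `write_model_config()`: `path`, invisibly.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(model_config, y)
}

#' @rdname read_model_config
#' @param config an [model_config()] to serialise.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "fthnet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
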