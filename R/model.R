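#' Y-Net architecture specification
#'
#' A U-Net with `depth` downsamplings (two 3x3 convolutions + ReLU and a 2x2
#' max-pool per contractive stage, channel count doubling each stage), a
#' mirrored expansive path with transposed-convolution upsampling and skip
#' connections, a 3-channel 1x1 output head (location logits, amplitude,
#' phase), and -- the Y branch -- a regression head at the end of the
#' contractive path: 3x3 convolution, ReLU, global average pooling and an
#' affine map to the six image-wide variables.
#'
#' @param depth Number of downsamplings; input height/width must be
#'   divisible by `2^depth`.
#' @param base_channels Channels of the first stage.
#' @param regression_dim Number of image-wide variables (6).
#' @return An object of class `ynet_spec`.
#' @export
ynet_spec <- function(depth = 4, base_channels = 32, regression_dim = 6) {
  stopifnot(depth >= 1, base_channels >= 1, regression_dim >= 1)
  structure(
    list(depth = as.integer(depth),
         base_channels = as.integer(base_channels),
         regression_dim = as.integer(regression_dim),
         image_out_channels = 3L),
    class = "ynet_spec"
  )
}

# shapes of every parameter tensor, in a fixed deterministic order;
# fan_in/fan_out include the receptive field, as Xavier prescribes
ynet_param_shapes <- function(spec) {
  D <- spec$depth
  ch <- spec$base_channels * 2^(0:D)   # ch[s] = channels of stage s; ch[D+1] bottleneck
  shapes <- list()
  add <- function(name, dim, fans) {
    shapes[[name]] <<- list(dim = dim, fans = fans)
  }
  prev <- 1L
  for (s in 1:D) {
    cs <- ch[s]
    add(sprintf("enc%d_c1_W", s), c(9 * prev, cs), c(9 * prev, 9 * cs))
    add(sprintf("enc%d_c1_b", s), cs, NULL)
    add(sprintf("enc%d_c2_W", s), c(9 * cs, cs), c(9 * cs, 9 * cs))
    add(sprintf("enc%d_c2_b", s), cs, NULL)
    prev <- cs
  }
  cb <- ch[D + 1]
  add("bot_c1_W", c(9 * ch[D], cb), c(9 * ch[D], 9 * cb))
  add("bot_c1_b", cb, NULL)
  add("bot_c2_W", c(9 * cb, cb), c(9 * cb, 9 * cb))
  add("bot_c2_b", cb, NULL)
  add("reg_c_W", c(9 * cb, cb), c(9 * cb, 9 * cb))
  add("reg_c_b", cb, NULL)
  add("reg_f_W", c(cb, spec$regression_dim), c(cb, spec$regression_dim))
  add("reg_f_b", spec$regression_dim, NULL)
  for (s in D:1) {
    cin <- ch[s + 1]
    cs <- ch[s]
    add(sprintf("up%d_W", s), c(cin, 4 * cs), c(4 * cin, 4 * cs))
    add(sprintf("up%d_b", s), cs, NULL)
    add(sprintf("dec%d_c1_W", s), c(9 * 2 * cs, cs), c(9 * 2 * cs, 9 * cs))
    add(sprintf("dec%d_c1_b", s), cs, NULL)
    add(sprintf("dec%d_c2_W", s), c(9 * cs, cs), c(9 * cs, 9 * cs))
    add(sprintf("dec%d_c2_b", s), cs, NULL)
  }
  add("out_W", c(ch[1], spec$image_out_channels),
      c(ch[1], spec$image_out_channels))
  add("out_b", spec$image_out_channels, NULL)
  shapes
}

#' Build a Y-Net with Xavier-initialized weights
#'
#' Weight tensors are drawn from the Xavier (Glorot) uniform distribution
#' `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))` (fans include the
#' receptive field), biases start at zero, and the whole draw is a pure
#' function of `init_seed`: two builds with the same seed are identical.
#'
#' @param spec A [ynet_spec()].
#' @param init_seed Integer seed for the initialization draw.
#' @return An object of class `ynet` with elements `params`, `spec`.
#' @examples
#' m <- build_ynet(ynet_spec(depth = 1, base_channels = 1), init_seed = 1)
#' n_parameters(m)
#' @export
build_ynet <- function(spec = ynet_spec(), init_seed = 1) {
  shapes <- ynet_param_shapes(spec)
  set.seed(init_seed)
  params <- lapply(shapes, function(sh) {
    if (is.null(sh$fans)) {
      matrix(0, nrow = 1, ncol = sh$dim)     # bias row vector
    } else {
      a <- sqrt(6 / sum(sh$fans))
      matrix(stats::runif(prod(sh$dim), -a, a), sh$dim[1], sh$dim[2])
    }
  })
  attr(params, "depth") <- spec$depth
  structure(list(params = params, spec = spec), class = "ynet")
}

#' Number of trainable parameters
#' @param model A [build_ynet()] model.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.ynet <- function(x, ...) {
  cat(sprintf("<ynet> depth %d, base %d channels, %d regression outputs, %s parameters\n",
              x$spec$depth, x$spec$base_channels, x$spec$regression_dim,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# accept a matrix, list of matrices, or H x W x B array; return H x W x B array
as_image_batch <- function(images) {
  if (is.list(images)) {
    images <- array(unlist(images, use.names = FALSE),
                    dim = c(dim(images[[1]]), length(images)))
  }
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1))
  stopifnot(length(dim(images)) == 3)
  images
}

#' Forward pass of the Y-Net
#'
#' Runs a batch of single-channel images through the network. The image head
#' yields three channels per pixel -- location logits (apply [sigmoid()] for
#' probabilities), estimated amplitude and estimated phase -- and the
#' regression head yields the six image-wide variables per image, on the
#' normalized [0, 1] scale. Deterministic for fixed weights.
#'
#' @param model A [build_ynet()] model (or `ynet_fit`).
#' @param images Matrix, list of matrices, or `H x W x B` array. Height and
#'   width must be divisible by `2^depth`.
#' @return An object of class `ynet_output`: list with `logit`, `amp`,
#'   `phase`, `prob` (`H x W x B` arrays) and `vars` (`B x 6` matrix).
#' @export
ynet_forward <- function(model, images) {
  model <- as_ynet(model)
  x <- as_image_batch(images)
  d <- model$spec$depth
  if (dim(x)[1] %% 2^d != 0 || dim(x)[2] %% 2^d != 0) {
    stop("image height and width must be divisible by 2^depth = ", 2^d,
         call. = FALSE)
  }
  out <- cpp_ynet_forward(model$params, x, d)
  structure(
    list(logit = out$logit, amp = out$amp, phase = out$phase,
         prob = sigmoid(out$logit), vars = out$vars),
    class = "ynet_output"
  )
}

#' Numerically stable logistic function
#' @param x Numeric.
#' @return `1 / (1 + exp(-x))`, computed without overflow.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out
}

# a ynet_fit carries the trained model in $model
as_ynet <- function(model) {
  if (inherits(model, "ynet_fit")) model$model else model
}

#' Save / load a Y-Net checkpoint
#'
#' Single-file checkpoint holding the weights and the architecture spec.
#'
#' @param model A `ynet` or `ynet_fit`.
#' @param path File path.
#' @return `load_ynet()` returns the model; `save_ynet()` the path,
#'   invisibly.
#' @export
save_ynet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ynet
#' @export
load_ynet <- function(path) {
  readRDS(path)
}
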