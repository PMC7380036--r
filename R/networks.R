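#' Convolutional stages of the identification pipeline
#'
#' Three convolutional networks drive the pipeline: a region-of-interest
#' stage that finds the whale's head in a downscaled image (5 convolutional
#' layers interspersed with 5 pooling layers, then a fully connected layer),
#' a keypoint stage that locates the bonnet tip and blowhole in the head crop
#' (9 convolutional layers, most followed by pooling, then a fully connected
#' layer), and an identity stage that classifies the passport photo
#' (11 convolutional layers, 6 pooling layers and a fully connected layer),
#' optionally with an auxiliary head predicting whether the callosity
#' pattern is connected.
#'
#' @name networks
NULL

# Convs per pooling block for each stage; one pool follows each block.
stage_blocks <- function(stage, n_pools = stage_default_pools(stage)) {
  n_convs <- switch(stage, roi = 5L, keypoint = 9L, identity = 11L,
                    stop("unknown stage: ", stage))
  if (stage == "roi" && n_pools != 5L) {
    stop("the roi stage uses exactly 5 pooling layers", call. = FALSE)
  }
  if (stage == "identity" && n_pools != 6L) {
    stop("the identity stage uses exactly 6 pooling layers", call. = FALSE)
  }
  if (n_pools < 1L || n_pools > n_convs) {
    stop(sprintf("stage '%s' supports 1..%d pooling layers", stage, n_convs),
         call. = FALSE)
  }
  # distribute convs over pooling blocks: a single conv before the first
  # pool (the full-resolution map is the expensive one), the rest spread
  # evenly with extras in the later, cheaper blocks
  if (n_pools == n_convs) return(rep(1L, n_pools))
  rest <- n_convs - 1L
  m <- n_pools - 1L
  base <- rest %/% m
  extra <- rest %% m
  c(1L, rep(base, m - extra), rep(base + 1L, extra))
}

stage_default_pools <- function(stage) {
  switch(stage, roi = 5L, keypoint = 3L, identity = 6L)
}

stage_default_widths <- function(stage) {
  switch(stage,
         roi = c(8, 12, 16, 24, 32),
         keypoint = c(8, 12, 16, 16, 24, 24, 32, 32, 32),
         identity = c(8, 12, 12, 16, 16, 24, 24, 32, 32, 48, 48))
}

stage_default_input <- function(stage) {
  switch(stage, roi = c(64, 64), keypoint = c(64, 64), identity = c(96, 96))
}

#' Describe a stage's architecture
#'
#' @param stage One of `"roi"`, `"keypoint"`, `"identity"`.
#' @param input_size `(H, W)` network input size.
#' @param widths Channel widths, one per convolutional layer; the length is
#'   fixed by the stage (5 / 9 / 11).
#' @param n_outputs Primary-head width (4 box values, 4 keypoint
#'   coordinates, or the number of identities).
#' @param aux_head Add the auxiliary connectivity head (identity stage).
#' @param n_pools Number of pooling layers. The roi and identity stages are
#'   fixed at their stated 5 and 6; the keypoint stage admits up to 9
#'   (default 3 — light pooling preserves the spatial precision that
#'   coordinate regression needs).
#' @return A `"network_spec"`: ordered layer descriptors plus head
#'   descriptors.
#' @export
network_spec <- function(stage = c("roi", "keypoint", "identity"),
                         input_size = stage_default_input(stage),
                         widths = stage_default_widths(stage),
                         n_outputs = NULL, aux_head = (stage == "identity"),
                         n_pools = stage_default_pools(stage)) {
  stage <- match.arg(stage)
  blocks <- stage_blocks(stage, n_pools)
  if (length(widths) != sum(blocks)) {
    stop(sprintf("stage '%s' needs %d conv widths, got %d", stage,
                 sum(blocks), length(widths)), call. = FALSE)
  }
  input_size <- check_size(input_size, "input_size")
  if (is.null(n_outputs)) {
    n_outputs <- switch(stage, roi = 4L, keypoint = 4L,
                        stop("`n_outputs` (number of identities) is required for the identity stage",
                             call. = FALSE))
  }
  layers <- list()
  hw <- input_size
  ci <- 3L
  k <- 0L
  for (b in seq_along(blocks)) {
    for (j in seq_len(blocks[b])) {
      k <- k + 1L
      layers[[length(layers) + 1L]] <- list(kind = "conv", kernel = 3L,
                                            c_in = ci, c_out = widths[k])
      layers[[length(layers) + 1L]] <- list(kind = "relu")
      ci <- widths[k]
    }
    if (any(hw < 2)) {
      stop(sprintf("input %d x %d too small for the pooling cascade: pool %d would act on a %d x %d map",
                   input_size[1], input_size[2], b, hw[1], hw[2]), call. = FALSE)
    }
    layers[[length(layers) + 1L]] <- list(kind = "pool", mode = "max")
    hw <- ceiling(hw / 2)
  }
  layers[[length(layers) + 1L]] <- list(kind = "flatten")
  n_features <- prod(hw) * ci
  heads <- list(primary = list(kind = switch(stage, roi = "bbox",
                                             keypoint = "keypoints",
                                             identity = "identity"),
                               n_out = as.integer(n_outputs)))
  if (stage == "identity" && isTRUE(aux_head)) {
    heads$connectivity <- list(kind = "connectivity", n_out = 1L)
  }
  structure(list(stage = stage, input_size = input_size, widths = widths,
                 layers = layers, heads = heads, n_features = n_features,
                 final_hw = hw),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  rp <- table(vapply(x$layers, `[[`, "", "kind"))
  cat(sprintf("<network_spec %s: input %d x %d, %s conv / %s pool, heads: %s>\n",
              x$stage, x$input_size[1], x$input_size[2],
              rp["conv"], rp["pool"], paste(names(x$heads), collapse = ", ")))
  invisible(x)
}

#' Build and initialize a pipeline stage network
#'
#' @param stage `"roi"`, `"keypoint"` or `"identity"`.
#' @param n_identities Roster size; required (>= 2) for the identity stage.
#' @param config Optional overrides: `input_size`, `widths`, `n_pools`
#'   (keypoint stage only), `seed` (initialization seed, default 1),
#'   `aux_head`, `aux_weight` (auxiliary loss weight, default 0.2),
#'   `roster` (identity labels).
#' @return A `"whale_network"` with seeded He-initialized parameters.
#' @export
build_stage <- function(stage = c("roi", "keypoint", "identity"),
                        n_identities = NULL, config = list()) {
  stage <- match.arg(stage)
  if (stage == "identity") {
    if (is.null(n_identities) && !is.null(config$roster)) {
      n_identities <- length(config$roster)
    }
    if (is.null(n_identities) || n_identities < 2) {
      stop("the identity stage needs `n_identities` >= 2", call. = FALSE)
    }
  }
  spec <- network_spec(
    stage,
    input_size = config$input_size %||% stage_default_input(stage),
    widths = config$widths %||% stage_default_widths(stage),
    n_outputs = if (stage == "identity") n_identities else NULL,
    aux_head = config$aux_head %||% (stage == "identity"),
    n_pools = config$n_pools %||% stage_default_pools(stage)
  )
  seed <- config$seed %||% 1L
  params <- with_seed(seed, {
    layers <- lapply(spec$layers, function(ld) {
      if (ld$kind == "conv") init_conv(ld$kernel, ld$kernel, ld$c_in, ld$c_out)
      else ld
    })
    heads <- lapply(spec$heads, function(hd) {
      b0 <- if (hd$kind %in% c("bbox", "keypoints")) 0.5 else 0
      c(init_fc(spec$n_features, hd$n_out, b_init = b0), kind = hd$kind)
    })
    list(layers = layers, heads = heads)
  })
  structure(list(stage = stage, spec = spec, layers = params$layers,
                 heads = params$heads, seed = seed,
                 aux_weight = config$aux_weight %||% 0.2,
                 roster = config$roster %||%
                   (if (stage == "identity") sprintf("whale_%03d", seq_len(n_identities)))),
            class = "whale_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.whale_network <- function(x, ...) {
  rp <- layer_report(x)
  cat(sprintf("<whale_network %s: %d conv, %d pool, %d fc; input %d x %d>\n",
              x$stage, sum(rp$kind == "conv"), sum(rp$kind == "pool"),
              sum(rp$kind == "fc"), x$spec$input_size[1], x$spec$input_size[2]))
  invisible(x)
}

#' Audit a built network's layer sequence
#'
#' Reports the actual instantiated layers in order (not the requested
#' specification), so tests can verify the stage honors its stated
#' architecture. The primary fully connected head is listed as kind `"fc"`;
#' the auxiliary connectivity head, when present, as `"aux_fc"`.
#'
#' @param network A `"whale_network"`.
#' @return A data frame with columns `position`, `kind`, `width`.
#' @export
layer_report <- function(network) {
  stopifnot(inherits(network, "whale_network"))
  rows <- lapply(network$layers, function(ly) {
    width <- if (ly$kind == "conv") dim(ly$w)[4] else NA_integer_
    data.frame(kind = ly$kind, width = width)
  })
  for (nm in names(network$heads)) {
    h <- network$heads[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = if (nm == "primary") "fc" else "aux_fc",
      width = nrow(h$w))
  }
  out <- do.call(rbind, rows)
  out$position <- seq_len(nrow(out))
  out[, c("position", "kind", "width")]
}

as_batch <- function(images, input_size) {
  if (is.list(images)) images <- stack_images(images)
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 4L || d[3] != 3L || d[1] != input_size[1] || d[2] != input_size[2]) {
    stop(sprintf("batch of size %s does not match network input %d x %d x 3",
                 paste(d, collapse = " x "), input_size[1], input_size[2]),
         call. = FALSE)
  }
  images
}

#' Run a network forward on a batch of images
#'
#' @param network A `"whale_network"`.
#' @param images An `(H, W, 3, N)` array, a single `H x W x 3` image, or a
#'   list of such images, matching the network's input size.
#' @return Head outputs: for the roi stage a list with `boxes` (`N x 4`
#'   normalized `(x0, y0, x1, y1)`, reconstructed from the regressed head
#'   axis) and `endpoints` (`N x 4` raw normalized bonnet/blowhole
#'   estimates); for the keypoint stage `keypoints`
#'   (`N x 4` normalized bonnet/blowhole coordinates); for the identity
#'   stage `probs` (`N x M` softmax rows summing to 1, columns named by the
#'   roster) and, when the auxiliary head is present, `connectivity`
#'   (`N` probabilities in `[0, 1]`).
#' @export
nn_forward <- function(network, images) {
  stopifnot(inherits(network, "whale_network"))
  x <- normalize_batch(as_batch(images, network$spec$input_size))
  f <- body_forward(network$layers, x, keep_cache = FALSE)$features
  z <- lapply(network$heads, function(h) h$w %*% f + h$b)
  if (network$stage == "identity") {
    p <- t(softmax_cols(z$primary))
    colnames(p) <- network$roster
    out <- list(probs = p)
    if (!is.null(z$connectivity)) out$connectivity <- as.numeric(sigmoid(z$connectivity))
    out
  } else if (network$stage == "roi") {
    e <- t(z$primary)
    boxes <- t(apply(e, 1, function(r) {
      p1 <- r[1:2]; p2 <- r[3:4]
      d <- p1 - p2
      hx <- 0.6 * abs(d[1]) + 0.677 * abs(d[2])
      hy <- 0.6 * abs(d[2]) + 0.677 * abs(d[1])
      c((p1[1] + p2[1]) / 2 - hx, (p1[2] + p2[2]) / 2 - hy,
        (p1[1] + p2[1]) / 2 + hx, (p1[2] + p2[2]) / 2 + hy)
    }))
    list(boxes = boxes, endpoints = e)
  } else {
    list(keypoints = t(z$primary))
  }
}

#' Feature maps of a network's convolutional prefix
#'
#' Runs only the first `n_layers` body layers (conv/relu/pool in report
#' order) and returns the resulting feature maps — useful for inspecting
#' translation equivariance of the convolutional part.
#'
#' @param network A `"whale_network"`.
#' @param images Input batch as in [nn_forward()].
#' @param n_layers How many body layers to apply.
#' @return An `(H, W, C, N)` feature array.
#' @export
forward_features <- function(network, images, n_layers) {
  stopifnot(inherits(network, "whale_network"),
            n_layers >= 1, n_layers <= length(network$layers))
  x <- normalize_batch(as_batch(images, network$spec$input_size))
  body_forward(network$layers[seq_len(n_layers)], x, keep_cache = FALSE)$features
}
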