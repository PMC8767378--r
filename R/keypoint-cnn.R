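# The 19-weight-layer landmark localization network: 16 3x3 convolution
# layers in five blocks, 5 max-pool layers (sizes 3,5,3,5,3; four stride-2
# reductions and one stride-1), global average pooling and 3 dense layers
# regressing each landmark's (x, y) normalized to [0, 1] through a sigmoid.
# A 224 x 224 x 3 input yields a 14 x 14 x 512 feature map at full width.

#' Landmark network configuration
#'
#' Defaults follow the published training configuration: Adam, learning rate
#' 0.001, 100 epochs, batch size 100, validation split 0.2, dropout 0.25
#' after each pooling stage, 3x3 filters throughout.
#'
#' @param view View whose landmark roster the head regresses.
#' @param input_size Square input side in px (default 224); must be a
#'   multiple of 16 (four spatial halvings).
#' @param channels Input channels (default 3).
#' @param width_scale Multiplier on block widths 64,128,256,512,512; reduced
#'   widths make CPU training tractable while preserving the architecture.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param learning_rate,epochs,batch_size,validation_split Training controls.
#' @param backbone Feature-extractor name; `"nasoform19"` is the hand-specified
#'   network (the only one provided).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @return `network_config` object.
#' @export
keypoint_network_config <- function(view = "lateral", input_size = 224,
                                    channels = 3, width_scale = 1,
                                    dropout = 0.25, learning_rate = 0.001,
                                    epochs = 100, batch_size = 100,
                                    validation_split = 0.2,
                                    backbone = "nasoform19", seed = 1L) {
  view <- match.arg(view, .nf_views)
  if (learning_rate <= 0)
    stop_nf("nf_config_error", "learning_rate must be > 0")
  if (dropout < 0 || dropout >= 1)
    stop_nf("nf_config_error", "dropout must be in [0, 1)")
  if (validation_split <= 0 || validation_split >= 1)
    stop_nf("nf_config_error", "validation_split must be in (0, 1)")
  if (input_size %% 16 != 0)
    stop_nf("nf_config_error", "input_size must be a multiple of 16 ",
            "(four stride-2 reductions), got ", input_size)
  if (backbone != "nasoform19")
    stop_nf("nf_config_error", "unknown backbone '", backbone,
            "'; only 'nasoform19' is provided")
  codes <- view_codes(view, include_optional = FALSE)
  structure(list(view = view, codes = codes, n_landmarks = length(codes),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels), width_scale = width_scale,
                 conv_per_block = c(2, 3, 3, 4, 4),
                 block_channels_base = c(64, 128, 256, 512, 512),
                 pool_sizes = c(3, 5, 3, 5, 3),
                 pool_strides = c(2, 2, 2, 2, 1),
                 fc_base = c(256, 128),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 validation_split = validation_split, backbone = backbone,
                 seed = as.integer(seed)),
            class = "network_config")
}

.nf_block_channels <- function(cfg)
  pmax(1L, round(cfg$block_channels_base * cfg$width_scale))

#' Build the landmark localization network
#'
#' Instantiates the feature extractor (16 convolutions, 5 pools) and the
#' 3-layer dense head, with weights drawn from a seeded He-scaled normal.
#'
#' @param cfg A [keypoint_network_config()].
#' @return A list of class `keypoint_net`: `layers`, `cfg`, and `summary`
#'   (a data frame of layer types, output shapes and parameter counts).
#' @export
build_keypoint_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  ch <- .nf_block_channels(cfg)
  layers <- list()
  side <- cfg$input_size
  in_ch <- cfg$channels
  rows <- list()
  note <- function(type, side, chn, n_par)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = type, out_h = side, out_w = side, out_ch = chn, params = n_par,
      stringsAsFactors = FALSE)
  for (b in seq_along(ch)) {
    for (i in seq_len(cfg$conv_per_block[b])) {
      l <- nn_conv_layer(in_ch, ch[b], k = 3, stride = 1, pad = 1)
      layers <- c(layers, list(l), list(nn_relu_layer()))
      note("conv3x3+relu", side, ch[b], length(l$W) + length(l$b))
      in_ch <- ch[b]
    }
    ps <- cfg$pool_sizes[b]; st <- cfg$pool_strides[b]
    layers <- c(layers, list(nn_maxpool_layer(ps, st)))
    side <- (side + 2 * ((ps - 1) %/% 2) - ps) %/% st + 1
    note(sprintf("maxpool%dx%d/s%d", ps, ps, st), side, in_ch, 0)
    if (cfg$dropout > 0) layers <- c(layers, list(nn_dropout_layer(cfg$dropout)))
  }
  layers <- c(layers, list(nn_gap_layer()))
  note("global_avg_pool", 1, in_ch, 0)
  fc <- pmax(4L, round(cfg$fc_base * cfg$width_scale))
  n_in <- in_ch
  for (f in fc) {
    l <- nn_dense_layer(n_in, f)
    layers <- c(layers, list(l), list(nn_relu_layer()))
    note("dense+relu", 1, f, length(l$W) + length(l$b))
    n_in <- f
  }
  out_dim <- 2L * cfg$n_landmarks
  l <- nn_dense_layer(n_in, out_dim)
  layers <- c(layers, list(l), list(nn_sigmoid_layer()))
  note("dense+sigmoid", 1, out_dim, length(l$W) + length(l$b))
  summary <- do.call(rbind, rows)
  structure(list(layers = layers, cfg = cfg, summary = summary),
            class = "keypoint_net")
}

#' @export
print.keypoint_net <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<keypoint_net> %s backbone, %s view: %d conv, %d dense, %d pool layers; %s parameters\n",
              x$cfg$backbone, x$cfg$view,
              sum(grepl("^conv", s$layer)), sum(grepl("^dense", s$layer)),
              sum(grepl("^maxpool", s$layer)), format(sum(s$params), big.mark = ",")))
  invisible(x)
}

# dataset sigma: SD of (pixel/255 - 0.5) over a sample of training images
.nf_dataset_sigma <- function(images) {
  v <- unlist(lapply(images[seq_len(min(20, length(images)))],
                     function(im) as.numeric(im)[seq(1, length(im), by = 7)]))
  s <- sd(v - 0.5)
  if (!isTRUE(s > 1e-6)) 1 else s
}

.nf_targets <- function(ls, codes, input_size) {
  p <- ls$points[codes, , drop = FALSE]
  as.numeric(t(p)) / (input_size - 1)   # x1,y1,x2,y2,... in [0,1]
}

#' Train the landmark network
#'
#' Mean-squared-error regression of normalized landmark coordinates with the
#' configured optimizer (Adam by default). Images are intensity-normalized
#' by the per-dataset pixel SD. Deterministic given `cfg$seed`.
#'
#' @param dataset A `keypoint_dataset` from [render_landmark_dataset()] (or
#'   a list with `images`, `landmark_sets`, `codes`).
#' @param cfg A [keypoint_network_config()]; its view must match the
#'   dataset.
#' @param net Optionally a pre-built [build_keypoint_network()] to continue
#'   training.
#' @return A list: `model` (class `keypoint_model`: layers + config +
#'   normalization constants) and `history` (per-epoch `train_loss`,
#'   `val_loss`, `val_mae_px`).
#' @export
train_keypoint_model <- function(dataset, cfg, net = NULL) {
  n <- length(dataset$images)
  if (n < 2) stop_nf("nf_data_error", "need at least 2 images to train")
  if (!identical(dataset$codes, cfg$codes))
    stop_nf("nf_config_error", "dataset landmark roster does not match cfg view")
  if (is.null(net)) net <- build_keypoint_network(cfg)
  layers <- net$layers
  set.seed(cfg$seed + 1L)
  sigma <- .nf_dataset_sigma(dataset$images)
  xs <- lapply(dataset$images, function(im) normalize_image(im * 255, sigma))
  ys <- lapply(dataset$landmark_sets, .nf_targets, codes = cfg$codes,
               input_size = cfg$input_size)
  idx <- sample.int(n)
  n_val <- max(1, round(cfg$validation_split * n))
  val <- idx[seq_len(n_val)]
  tr <- setdiff(idx, val)
  if (!length(tr)) { tr <- val }   # degenerate tiny datasets
  state <- nn_adam_init(layers)
  t_step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_mae_px = numeric(0))
  eval_set <- function(ids, layers) {
    tl <- 0; mae <- 0
    for (i in ids) {
      out <- nn_forward(layers, xs[[i]])$out
      tl <- tl + nn_mse(out, ys[[i]])$loss
      mae <- mae + mean(abs(out - ys[[i]])) * (cfg$input_size - 1)
    }
    c(loss = tl / length(ids), mae = mae / length(ids))
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (i in batch) {
        fw <- nn_forward(layers, xs[[i]], train = TRUE)
        ls <- nn_mse(fw$out, ys[[i]])
        bl <- bl + ls$loss
        bw <- nn_backward(layers, fw$caches, ls$dpred)
        acc <- nn_grads_add(acc, bw$grads, 1 / length(batch))
      }
      t_step <- t_step + 1
      up <- nn_update(layers, acc, state, cfg$learning_rate, t_step, "adam")
      layers <- up$layers; state <- up$state
      ep_loss <- ep_loss + bl / length(batch)
    }
    ev <- eval_set(val, layers)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(batches),
                                   val_loss = ev["loss"], val_mae_px = ev["mae"]))
  }
  rownames(hist) <- NULL
  model <- structure(list(layers = layers, cfg = cfg, sigma = sigma),
                     class = "keypoint_model")
  list(model = model, history = hist)
}

# aspect-preserving resize + centered padding of an image to a square side;
# returns list(image, scale, off_x, off_y) for coordinate back-mapping
.nf_fit_to_input <- function(img, side, channels) {
  img <- .nf_as_cube(img)
  d <- dim(img)
  if (d[3] != channels)
    stop_nf("nf_input_error", "expected ", channels, " channel(s), got ", d[3])
  scale <- side / max(d[1], d[2])
  nh <- max(1, round(d[1] * scale)); nw <- max(1, round(d[2] * scale))
  rs <- cpp_resize_bilinear(img, nh, nw)
  off_y <- (side - nh) %/% 2; off_x <- (side - nw) %/% 2
  canvas <- array(0, c(side, side, channels))
  canvas[off_y + seq_len(nh), off_x + seq_len(nw), ] <- rs
  list(image = canvas, scale_x = nw / d[2], scale_y = nh / d[1],
       off_x = off_x, off_y = off_y, orig = d)
}

#' Predict landmarks on an image
#'
#' Resizes the image to the network input (aspect preserved, centered
#' zero padding), runs the network, and maps predicted coordinates back
#' through the inverse transform into the original pixel frame, clamped to
#' the image bounds.
#'
#' @param model A `keypoint_model` from [train_keypoint_model()].
#' @param image `h x w (x c)` array in `[0, 1]`.
#' @param view View tag for the returned set (defaults to the model's).
#' @param subject_id Identifier for the returned set.
#' @return A [landmark_set()] with all non-optional catalog codes for the
#'   view and uniform confidence 1 placeholders.
#' @export
predict_landmarks <- function(model, image, view = model$cfg$view,
                              subject_id = "predicted") {
  stopifnot(inherits(model, "keypoint_model"))
  cfg <- model$cfg
  fit <- .nf_fit_to_input(image, cfg$input_size, cfg$channels)
  x <- normalize_image(fit$image * 255, model$sigma)
  out <- nn_forward(model$layers, x)$out * (cfg$input_size - 1)
  xy <- matrix(out, ncol = 2, byrow = TRUE)
  xy[, 1] <- (xy[, 1] - fit$off_x) / fit$scale_x
  xy[, 2] <- (xy[, 2] - fit$off_y) / fit$scale_y
  xy[, 1] <- pmin(pmax(xy[, 1], 0), fit$orig[2] - 1)
  xy[, 2] <- pmin(pmax(xy[, 2], 0), fit$orig[1] - 1)
  rownames(xy) <- cfg$codes
  landmark_set(subject_id, view, xy,
               confidence = setNames(rep(1, length(cfg$codes)), cfg$codes))
}
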