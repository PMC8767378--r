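# Back-propagation network predicting nasal-bone morphology from surface
# measurements and body covariates. A fully connected trunk with ReLU
# hidden layers and per-layer biases feeds three heads: linear regression
# of bone dimensions, and softmax classification of the frontal type (A-E)
# and lateral shape (V/S). Training is plain back-propagation
# (W <- W - f * dE/dW) or Adam; inputs and regression targets are z-scored
# on the training data.

.nf_bpnn_feature_default <- function() {
  c("age", "sex", "height", "weight", "bmi",
    gsub("-", "_", paste0("surf_", .nf_surface_codes)),
    gsub("-", "_", paste0("ang_", .nf_angle_codes)))
}

# S-K and K-R exist only for kyphion-bearing subjects; the regression head
# predicts the six dims defined for everyone.
.nf_bpnn_target_default <- function()
  paste0("bone_", c("n_s", "s_r", "n_r", "d3", "d4", "d5"))

#' BPNN configuration
#'
#' @param features Ordered input feature columns (covariates plus surface
#'   measurements/angles as named in a `subject_table`).
#' @param targets Bone-dimension columns for the regression head.
#' @param hidden Hidden layer sizes (positive; at least one layer).
#' @param learning_rate Step size `f` of the update `W <- W - f dE/dW`.
#' @param epochs,batch_size Training controls.
#' @param optimizer `"adam"` (default; the published training configuration
#'   uses Adam throughout) or `"sgd"` (plain gradient descent).
#' @param lr_decay Multiplier applied to the learning rate over the final
#'   30% of epochs (fine-tuning phase); 1 disables.
#' @param tol Tolerable-error early stop: training stops when the epoch
#'   loss falls below it (0 disables).
#' @param seed Integer seed (weight init + shuffling).
#' @return `bpnn_config` object.
#' @export
bpnn_config <- function(features = .nf_bpnn_feature_default(),
                        targets = .nf_bpnn_target_default(),
                        hidden = c(128, 64), learning_rate = 0.002,
                        epochs = 400, batch_size = 128,
                        optimizer = c("adam", "sgd"), tol = 0,
                        lr_decay = 0.2, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (!length(features)) stop_nf("nf_config_error", "feature list must be non-empty")
  if (!length(hidden) || any(hidden < 1))
    stop_nf("nf_config_error", "hidden sizes must be positive (at least one hidden layer)")
  if (learning_rate <= 0) stop_nf("nf_config_error", "learning_rate must be > 0")
  structure(list(features = features, targets = targets,
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, tol = tol, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

#' Build a BPNN
#'
#' Seeded He-initialized weights; biases zero. Parameter count is
#' `sum over layers (n_in * n_out + n_out)` including the three heads.
#'
#' @param cfg A [bpnn_config()].
#' @param n_classes_frontal,n_classes_lateral Classification head widths.
#' @return `bpnn` object with trunk weights `W`, `b` and head weights.
#' @export
build_bpnn <- function(cfg, n_classes_frontal = 5, n_classes_lateral = 2) {
  stopifnot(inherits(cfg, "bpnn_config"))
  set.seed(cfg$seed)
  sizes <- c(length(cfg$features), cfg$hidden)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(.nf_he_init(sizes[l], c(sizes[l], sizes[l + 1])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  last <- tail(sizes, 1)
  head_ <- function(n_out)
    list(W = matrix(.nf_he_init(last, c(last, n_out)), last, n_out),
         b = rep(0, n_out))
  structure(list(W = W, b = b,
                 reg = head_(length(cfg$targets)),
                 front = head_(n_classes_frontal),
                 lat = head_(n_classes_lateral),
                 cfg = cfg, scaling = NULL),
            class = "bpnn")
}

#' Number of parameters of a BPNN
#' @param model A `bpnn`.
#' @return Integer parameter count.
#' @export
bpnn_n_params <- function(model) {
  n <- sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
  for (h in list(model$reg, model$front, model$lat))
    n <- n + length(h$W) + length(h$b)
  as.integer(n)
}

.nf_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward over a feature matrix X (n x p); returns activations
.nf_bpnn_forward <- function(model, X) {
  H <- list(X)
  A <- X
  for (l in seq_along(model$W)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], `+`)
    A <- relu(Z)
    H[[l + 1]] <- A
  }
  reg <- sweep(A %*% model$reg$W, 2, model$reg$b, `+`)
  pf <- .nf_softmax(sweep(A %*% model$front$W, 2, model$front$b, `+`))
  pl <- .nf_softmax(sweep(A %*% model$lat$W, 2, model$lat$b, `+`))
  list(H = H, reg = reg, p_front = pf, p_lat = pl)
}

# combined loss: mean MSE over regression outputs + mean cross-entropy per
# classification head. Yf / Yl are one-hot matrices.
.nf_bpnn_loss <- function(fw, Y, Yf, Yl) {
  n <- nrow(Y)
  mse <- mean((fw$reg - Y)^2)
  ce_f <- -mean(log(pmax(rowSums(fw$p_front * Yf), 1e-12)))
  ce_l <- -mean(log(pmax(rowSums(fw$p_lat * Yl), 1e-12)))
  mse + ce_f + ce_l
}

# analytic gradients of .nf_bpnn_loss wrt all weights
.nf_bpnn_backward <- function(model, fw, Y, Yf, Yl) {
  n <- nrow(Y)
  A <- fw$H[[length(fw$H)]]
  d_reg <- 2 * (fw$reg - Y) / (n * ncol(Y))
  d_f <- (fw$p_front - Yf) / n
  d_l <- (fw$p_lat - Yl) / n
  g <- list(reg = list(dW = crossprod(A, d_reg), db = colSums(d_reg)),
            front = list(dW = crossprod(A, d_f), db = colSums(d_f)),
            lat = list(dW = crossprod(A, d_l), db = colSums(d_l)))
  dA <- tcrossprod(d_reg, model$reg$W) + tcrossprod(d_f, model$front$W) +
        tcrossprod(d_l, model$lat$W)
  dW <- list(); db <- list()
  for (l in rev(seq_along(model$W))) {
    dZ <- dA * (fw$H[[l + 1]] > 0)
    dW[[l]] <- crossprod(fw$H[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, model$W[[l]])
  }
  g$W <- dW; g$b <- db
  g
}

.nf_onehot <- function(f, levels) {
  M <- matrix(0, length(f), length(levels), dimnames = list(NULL, levels))
  M[cbind(seq_along(f), match(f, levels))] <- 1
  M
}

.nf_bpnn_design <- function(subjects, features) {
  X <- matrix(NA_real_, nrow(subjects), length(features),
              dimnames = list(NULL, features))
  for (f in features) {
    if (!f %in% colnames(subjects))
      stop_nf("nf_feature_error", "missing feature '", f, "' in subject table")
    v <- subjects[[f]]
    if (f == "sex") v <- as.numeric(v == "M")
    X[, f] <- as.numeric(v)
  }
  X
}

#' Train the BPNN on a subject table
#'
#' Features and regression targets are z-scored on the training data
#' (scaling constants are stored in the model); zero-variance features are
#' dropped with a warning. The loss is the summed mean-squared regression
#' error and the two classification cross-entropies; weights follow
#' back-propagation updates with the configured optimizer.
#'
#' @param subjects A `subject_table` with at least 10 rows carrying the
#'   configured features, bone targets and class labels.
#' @param cfg A [bpnn_config()].
#' @return List: `model` (a trained `bpnn` with embedded scaling) and
#'   `history` (per-epoch loss).
#' @export
train_bpnn <- function(subjects, cfg = bpnn_config()) {
  if (nrow(subjects) < 10)
    stop_nf("nf_data_error", "need at least 10 training records")
  X <- .nf_bpnn_design(subjects, cfg$features)
  keep <- apply(X, 2, sd) > 1e-12
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(cfg$features[!keep], collapse = ", "))
    cfg$features <- cfg$features[keep]
    X <- X[, keep, drop = FALSE]
  }
  mu_x <- colMeans(X); sd_x <- apply(X, 2, sd)
  Xs <- scale(X, mu_x, sd_x)
  Y <- as.matrix(subjects[, cfg$targets, drop = FALSE])
  if (any(is.na(Y))) stop_nf("nf_data_error", "NA in regression targets")
  mu_y <- colMeans(Y); sd_y <- pmax(apply(Y, 2, sd), 1e-12)
  Ys <- scale(Y, mu_y, sd_y)
  f_levels <- c("A", "B", "C", "D", "E"); l_levels <- c("V", "S")
  Yf <- .nf_onehot(subjects$frontal_type, f_levels)
  Yl <- .nf_onehot(subjects$lateral_shape, l_levels)

  model <- build_bpnn(cfg)
  set.seed(cfg$seed + 1L)
  n <- nrow(Xs)
  adam <- list()  # per-parameter moment state, built lazily
  t_step <- 0
  hist <- numeric(0)
  params_get <- function() c(model$W, model$b,
                             list(model$reg$W, model$reg$b, model$front$W,
                                  model$front$b, model$lat$W, model$lat$b))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      if (epoch > 0.7 * cfg$epochs) (cfg$lr_decay %||% 1) else 1
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      fw <- .nf_bpnn_forward(model, Xs[batch, , drop = FALSE])
      ep_loss <- ep_loss + .nf_bpnn_loss(fw, Ys[batch, , drop = FALSE],
                                         Yf[batch, , drop = FALSE],
                                         Yl[batch, , drop = FALSE])
      g <- .nf_bpnn_backward(model, fw, Ys[batch, , drop = FALSE],
                             Yf[batch, , drop = FALSE], Yl[batch, , drop = FALSE])
      t_step <- t_step + 1
      upd <- function(P, G, key) {
        if (cfg$optimizer == "sgd") return(P - lr * G)
        s <- adam[[key]] %||% list(m = P * 0, v = P * 0)
        s$m <- 0.9 * s$m + 0.1 * G
        s$v <- 0.999 * s$v + 0.001 * G^2
        adam[[key]] <<- s
        mh <- s$m / (1 - 0.9^t_step); vh <- s$v / (1 - 0.999^t_step)
        P - lr * mh / (sqrt(vh) + 1e-8)
      }
      for (l in seq_along(model$W)) {
        model$W[[l]] <- upd(model$W[[l]], g$W[[l]], paste0("W", l))
        model$b[[l]] <- upd(model$b[[l]], g$b[[l]], paste0("b", l))
      }
      for (h in c("reg", "front", "lat")) {
        model[[h]]$W <- upd(model[[h]]$W, g[[h]]$dW, paste0(h, "W"))
        model[[h]]$b <- upd(model[[h]]$b, g[[h]]$db, paste0(h, "b"))
      }
    }
    ep_loss <- ep_loss / length(batches)
    hist <- c(hist, ep_loss)
    if (cfg$tol > 0 && ep_loss < cfg$tol) break
  }
  model$scaling <- list(mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
                        f_levels = f_levels, l_levels = l_levels)
  model$cfg <- cfg
  list(model = model,
       history = data.frame(epoch = seq_along(hist), loss = hist))
}

#' Gradient check of the BPNN loss
#'
#' Analytic back-propagated gradients versus central finite differences of
#' the combined loss, over every parameter; maximum relative error.
#'
#' @param model A `bpnn` (keep it small).
#' @param X Feature matrix (few rows).
#' @param Y Regression target matrix.
#' @param front,lat Class label vectors.
#' @param eps Perturbation.
#' @return Max relative gradient error.
#' @export
bpnn_gradcheck <- function(model, X, Y, front, lat, eps = 1e-5) {
  Yf <- .nf_onehot(front, c("A", "B", "C", "D", "E"))
  Yl <- .nf_onehot(lat, c("V", "S"))
  fw <- .nf_bpnn_forward(model, X)
  g <- .nf_bpnn_backward(model, fw, Y, Yf, Yl)
  loss_at <- function(m) .nf_bpnn_loss(.nf_bpnn_forward(m, X), Y, Yf, Yl)
  worst <- 0
  check <- function(getp, setp, G) {
    P <- getp(model)
    for (j in seq_along(P)) {
      m2 <- model; P2 <- P; P2[j] <- P[j] + eps; m2 <- setp(m2, P2)
      lp <- loss_at(m2)
      P2[j] <- P[j] - eps; m2 <- setp(m2, P2)
      lm <- loss_at(m2)
      gN <- (lp - lm) / (2 * eps)
      rel <- abs(G[j] - gN) / max(abs(G[j]) + abs(gN), 1e-8)
      if (rel > worst) worst <<- rel
    }
  }
  for (l in seq_along(model$W)) {
    check(function(m) m$W[[l]], function(m, p) { m$W[[l]] <- matrix(p, nrow(m$W[[l]])); m }, g$W[[l]])
    check(function(m) m$b[[l]], function(m, p) { m$b[[l]] <- p; m }, g$b[[l]])
  }
  for (h in c("reg", "front", "lat")) {
    check(function(m) m[[h]]$W, function(m, p) { m[[h]]$W <- matrix(p, nrow(m[[h]]$W)); m }, g[[h]]$dW)
    check(function(m) m[[h]]$b, function(m, p) { m[[h]]$b <- p; m }, g[[h]]$db)
  }
  worst
}

#' Predict bone morphology for subjects
#'
#' Runs the trained BPNN on records carrying the configured features
#' (bone fields are not required) and returns de-standardized bone
#' dimension predictions, class probabilities, and hard labels (argmax;
#' ties break toward the earlier class letter / V).
#'
#' @param model A trained `bpnn`.
#' @param records A `subject_table` (bone columns ignored if present).
#' @return A list of class `morphology_result`: `bone_dims` (matrix, mm),
#'   `frontal_type`, `lateral_shape`, `prob_frontal`, `prob_lateral`.
#' @export
predict_bone_morphology <- function(model, records) {
  stopifnot(inherits(model, "bpnn"))
  if (is.null(model$scaling))
    stop_nf("nf_logic_error", "model has not been trained")
  X <- .nf_bpnn_design(records, model$cfg$features)
  Xs <- scale(X, model$scaling$mu_x, model$scaling$sd_x)
  fw <- .nf_bpnn_forward(model, Xs)
  bone <- sweep(sweep(fw$reg, 2, model$scaling$sd_y, `*`), 2,
                model$scaling$mu_y, `+`)
  colnames(bone) <- model$cfg$targets
  structure(list(
    subject_id = records$subject_id,
    bone_dims = bone,
    frontal_type = model$scaling$f_levels[apply(fw$p_front, 1, which.max)],
    lateral_shape = model$scaling$l_levels[apply(fw$p_lat, 1, which.max)],
    prob_frontal = fw$p_front,
    prob_lateral = fw$p_lat), class = "morphology_result")
}
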