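# cell_cycle_classifier: two-stage phase assignment.
# Stage 1: shallow neural network (hidden sizes 30 and 10, tanh, softmax over
# 5 classes) separates interphase from four mitotic classes.
# Stage 2: constrained mixture of 8 Gaussians + uniform background in
# (area, I_DAPI) assigns interphase cells to G1/S/G2.

MITOSIS_CLASSES <- c("interphase", "prometaphase", "metaphase",
                     "early_anaphase", "late_anaphase")

# ---- shallow MLP -------------------------------------------------------------

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                           sqrt(1 / sizes[l])), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% par$W[[l]] + rep(par$b[[l]], each = nrow(X))
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  Z <- A[[L + 1L]]
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(P = P, A = A)
}

mlp_loss_grad <- function(par, X, Y) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  P <- fw$P; A <- fw$A
  loss <- -mean(log(pmax(P[Y == 1], 1e-12)))
  L <- length(par$W)
  dZ <- (P - Y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(A[[l]]) %*% dZ
    gb[[l]] <- colSums(dZ)
    if (l > 1) dZ <- (dZ %*% t(par$W[[l]])) * (1 - A[[l]]^2)
  }
  list(loss = loss, gW = gW, gb = gb)
}

mlp_train <- function(X, Y, Xval, Yval, hidden = c(30L, 10L), lr = 0.01,
                      max_epochs = 1000L, patience = 6L) {
  par <- mlp_init(ncol(X), hidden, ncol(Y))
  L <- length(par$W)
  mW <- vW <- lapply(par$W, function(w) w * 0)
  mb <- vb <- lapply(par$b, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(par = par, val = Inf, epoch = 0L)
  bad <- 0L
  hist_val <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    g <- mlp_loss_grad(par, X, Y)
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhb <- mb[[l]] / (1 - b1^ep); vhb <- vb[[l]] / (1 - b2^ep)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    vp <- mlp_forward(par, Xval)$P
    vloss <- -mean(log(pmax(vp[Yval == 1], 1e-12)))
    hist_val <- c(hist_val, vloss)
    if (vloss < best$val - 1e-6) {
      best <- list(par = par, val = vloss, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  list(par = best$par, val_loss = best$val, stopped_epoch = ep,
       best_epoch = best$epoch, val_history = hist_val)
}

# feature columns used by the mitosis classifier (everything numeric that is
# defined for every nucleus and scale-appropriate)
classifier_feature_columns <- function(records) {
  drop <- c("nucleus_id", "row", "col", "x_um", "y_um", "slow_um", "qc_pass",
            "i_gh2ax", "i_gh2ax_raw", "i_dapi_raw", "phase", "nn_class",
            "label", "damage",
            grep("^gh2ax_", names(records), value = TRUE))
  keep <- setdiff(names(records), drop)
  keep[vapply(records[keep], is.numeric, logical(1))]
}

#' Train the five-class mitosis classifier
#'
#' Stratified 0.7/0.15/0.15 train/validation/test split, feature
#' standardization from the training split only, Adam full-batch training of
#' a tanh network with hidden sizes 30 and 10 and a softmax output, early
#' stopping when the validation loss fails to improve for \code{patience}
#' consecutive epochs.
#'
#' @param records feature table (\code{\link{extract_features}} output).
#' @param labels integer class labels 1..5 (1 = interphase, 2 = prometaphase,
#'   3 = metaphase, 4 = early anaphase, 5 = late anaphase/telophase/early G1)
#'   or a factor over \code{MITOSIS_CLASSES}.
#' @param split train/validation/test fractions, summing to 1.
#' @param seed integer; fixes the split and the weight initialization.
#' @param hidden hidden-layer sizes.
#' @param patience early-stopping patience, epochs.
#' @param max_epochs epoch cap.
#' @return object of class \code{mitosis_classifier}: weights, normalization,
#'   feature schema, split indices, held-out confusion matrix and accuracy.
#' @export
train_mitosis_classifier <- function(records, labels, split = c(0.7, 0.15, 0.15),
                                     seed = 1L, hidden = c(30L, 10L),
                                     patience = 6L, max_epochs = 1000L) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  y <- if (is.factor(labels) || is.character(labels))
    as.integer(factor(labels, levels = MITOSIS_CLASSES)) else as.integer(labels)
  if (anyNA(y) || any(y < 1L | y > 5L)) stop("labels must be classes 1..5")
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  tab <- table(factor(y, levels = 1:5))
  small <- names(tab)[tab > 0 & tab < 10]
  if (length(small) > 0)
    stop("class ", MITOSIS_CLASSES[as.integer(small[1])],
         " has fewer than 10 examples")
  cols <- classifier_feature_columns(records)
  X <- as.matrix(records[, cols, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  set.seed(child_seed(seed, 1L))
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (k in sort(unique(y))) {
    ik <- sample(which(y == k))
    n <- length(ik)
    n_tr <- round(split[1] * n); n_va <- round(split[2] * n)
    idx$train <- c(idx$train, ik[seq_len(n_tr)])
    idx$val <- c(idx$val, ik[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, ik[(n_tr + n_va + 1):n])
  }
  mu <- colMeans(X[idx$train, , drop = FALSE])
  sg <- apply(X[idx$train, , drop = FALSE], 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  onehot <- function(yy) {
    Y <- matrix(0, length(yy), 5L)
    Y[cbind(seq_along(yy), yy)] <- 1
    Y
  }
  set.seed(child_seed(seed, 2L))
  fit <- mlp_train(Z[idx$train, , drop = FALSE], onehot(y[idx$train]),
                   Z[idx$val, , drop = FALSE], onehot(y[idx$val]),
                   hidden = hidden, patience = patience,
                   max_epochs = max_epochs)
  Pte <- mlp_forward(fit$par, Z[idx$test, , drop = FALSE])$P
  pred <- max.col(Pte, ties.method = "first")
  cm <- table(truth = factor(y[idx$test], 1:5), pred = factor(pred, 1:5))
  structure(list(par = fit$par, feature_columns = cols, mu = mu, sigma = sg,
                 hidden = hidden, classes = MITOSIS_CLASSES,
                 split_idx = idx, seed = seed,
                 confusion = cm, test_accuracy = sum(diag(cm)) / sum(cm),
                 training = fit[c("val_loss", "stopped_epoch", "best_epoch")]),
            class = "mitosis_classifier")
}

#' Classify nuclei into the five mitosis classes
#'
#' @param model \code{mitosis_classifier}.
#' @param records feature table with the training schema's columns.
#' @return list: \code{class} (integer 1..5), \code{prob} (n x 5 softmax
#'   matrix).
#' @export
classify_mitosis <- function(model, records) {
  miss <- setdiff(model$feature_columns, names(records))
  if (length(miss) > 0)
    stop("records are missing feature columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(records[, model$feature_columns, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  cls <- rep(NA_integer_, nrow(Z))
  P <- matrix(NA_real_, nrow(Z), 5L)
  ok <- stats::complete.cases(Z)
  if (any(ok)) {
    P[ok, ] <- mlp_forward(model$par, Z[ok, , drop = FALSE])$P
    cls[ok] <- max.col(P[ok, , drop = FALSE], ties.method = "first")
  }
  list(class = cls, prob = P)
}

# ---- constrained mixture of Gaussians + uniform background -------------------

dmvnorm2 <- function(X, mu, S) {
  # 2D Gaussian density, closed form
  a <- S[1, 1]; b <- S[1, 2]; d <- S[2, 2]
  det <- a * d - b * b
  if (det <= 0) return(rep(0, nrow(X)))
  dx <- X[, 1] - mu[1]; dy <- X[, 2] - mu[2]
  q <- (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# spacing parameters: components 1..7 at t = 0, 1/6, ..., 1 on the G1->G2
# segment; component 8 fixed at the G1 peak (t = 0)
MOG_T <- c(seq(0, 1, length.out = 7), 0)

mog_means <- function(g1, g2) {
  t(vapply(MOG_T, function(t) (1 - t) * g1 + t * g2, numeric(2)))
}

#' Fit the constrained 8-Gaussian + uniform interphase model
#'
#' EM in (area, corrected I_DAPI) space. Means are constrained throughout:
#' components 1..7 are equally spaced on the segment joining the G1 and G2
#' peaks (endpoints included) and component 8 sits on the G1 peak; the
#' constrained M-step solves the 4-unknown weighted normal equations for the
#' two endpoints, so the log-likelihood is non-decreasing every iteration.
#' The uniform background has density 1/area of the support box.
#'
#' @param records interphase nucleus table with \code{area_um2} and corrected
#'   \code{i_dapi} (G1 near 1, G2 near 2).
#' @param seed integer (initialization is deterministic; the seed is recorded).
#' @param min_records minimum number of interphase records.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return object of class \code{interphase_mog}: endpoints, means,
#'   covariances, weights, background weight, support box, log-likelihood
#'   trace, component-to-phase mapping.
#' @export
fit_interphase_mog <- function(records, seed = 1L, min_records = 2000L,
                               max_iter = 300L, tol = 1e-8) {
  stopifnot(all(c("area_um2", "i_dapi") %in% names(records)))
  X <- cbind(records$area_um2, records$i_dapi)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < min_records)
    stop("need at least ", min_records, " interphase records")
  if (any(apply(X, 2, sd) <= 0) || !all(is.finite(X)))
    stop("degenerate input: zero variance in area or I_DAPI")
  # G1 / G2 peaks from the marginal modes nearest I_DAPI = 1 and 2
  g1_sel <- X[, 2] >= 0.7 & X[, 2] <= 1.3
  g2_sel <- X[, 2] >= 1.6 & X[, 2] <= 2.5
  if (sum(g2_sel) < 50L || sum(g1_sel) < 50L)
    stop("G1 or G2 peak undetectable (is the DAPI intensity corrected and bimodal?)")
  g1 <- c(density_mode(X[g1_sel, 1]), density_mode(X[g1_sel, 2]))
  g2 <- c(density_mode(X[g2_sel, 1]), density_mode(X[g2_sel, 2]))
  means <- mog_means(g1, g2)
  s_area <- sd(X[g1_sel, 1]); s_int <- sd(X[g1_sel, 2])
  covs <- replicate(8, diag(c(s_area^2, s_int^2)), simplify = FALSE)
  w <- rep(0.95 / 8, 8)
  w0 <- 0.05
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  pad <- 0.05 * (hi - lo)
  box <- rbind(lo - pad, hi + pad)
  u_dens <- 1 / prod(box[2, ] - box[1, ])
  n <- nrow(X)
  ll_trace <- numeric(0)
  ridge <- diag(c((0.02 * s_area)^2, (0.02 * s_int)^2))
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:8, function(j) w[j] * dmvnorm2(X, means[j, ], covs[[j]]),
                   numeric(n))
    dbg <- w0 * u_dens
    tot <- rowSums(dens) + dbg
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && (ll - ll_trace[it - 1L]) < tol * abs(ll_trace[it - 1L]) &&
        ll >= ll_trace[it - 1L]) break
    R <- dens / tot                      # n x 8 responsibilities
    r0 <- dbg / tot
    wj <- colSums(R)
    # constrained M-step for the endpoints theta = (g1, g2):
    # sum_j B_j' S_j^-1 B_j w_j theta = sum_j B_j' S_j^-1 (w_j m_j)
    A <- matrix(0, 4, 4); rhs <- numeric(4)
    for (j in 1:8) {
      if (wj[j] <= 1e-12) next
      Sj_inv <- solve(covs[[j]])
      tj <- MOG_T[j]
      B <- cbind((1 - tj) * diag(2), tj * diag(2))
      mj <- colSums(R[, j] * X) / wj[j]
      A <- A + wj[j] * t(B) %*% Sj_inv %*% B
      rhs <- rhs + wj[j] * t(B) %*% Sj_inv %*% mj
    }
    theta <- solve(A, rhs)
    g1 <- theta[1:2]; g2 <- theta[3:4]
    means <- mog_means(g1, g2)
    for (j in 1:8) {
      if (wj[j] <= 1e-12) next
      dxy <- sweep(X, 2, means[j, ])
      covs[[j]] <- crossprod(dxy * R[, j], dxy) / wj[j] + ridge
    }
    w <- wj / n
    w0 <- sum(r0) / n
  }
  structure(list(g1 = g1, g2 = g2, means = means, covs = covs,
                 weights = w, background_weight = w0, box = box,
                 uniform_density = u_dens, loglik = ll_trace, seed = seed,
                 phase_map = c("G1", "S", "S", "S", "S", "S", "G2", "G1")),
            class = "interphase_mog")
}

#' Classify interphase nuclei into G1 / S / G2
#'
#' Posterior over the 8 Gaussians plus the uniform background; phase follows
#' the component mapping (components 1 and 8 at the G1 peak -> G1,
#' components 2..6 -> S, component 7 at the G2 peak -> G2).
#' Background-dominated records are flagged unclassified (\code{NA} phase).
#'
#' @param model \code{interphase_mog}.
#' @param records table with \code{area_um2} and corrected \code{i_dapi}.
#' @return list: \code{phase} (character, \code{NA} = unclassified),
#'   \code{posterior} (n x 9 matrix, last column = background),
#'   \code{component} (argmax component, 0 = background).
#' @export
classify_interphase <- function(model, records) {
  X <- cbind(records$area_um2, records$i_dapi)
  n <- nrow(X)
  dens <- vapply(1:8, function(j)
    model$weights[j] * dmvnorm2(X, model$means[j, ], model$covs[[j]]), numeric(n))
  if (n == 1L) dens <- matrix(dens, 1)
  dbg <- rep(model$background_weight * model$uniform_density, n)
  tot <- rowSums(dens) + dbg
  post <- cbind(dens, dbg) / tot
  comp <- max.col(post, ties.method = "first")
  phase <- ifelse(comp == 9L, NA_character_, model$phase_map[pmin(comp, 8L)])
  list(phase = phase, posterior = post,
       component = ifelse(comp == 9L, 0L, comp))
}

#' Two-stage phase assignment for a whole record table
#'
#' Runs the mitosis network on every record; interphase records (class 1)
#' are then assigned G1/S/G2 by the constrained mixture model (fitted here if
#' not supplied). Mitotic records get phase \code{"M"}.
#'
#' @param records feature table with corrected intensities.
#' @param nn_model \code{mitosis_classifier}.
#' @param mog optional pre-fitted \code{interphase_mog}.
#' @param seed passed to \code{\link{fit_interphase_mog}}.
#' @return list: \code{records} with \code{nn_class} and \code{phase}
#'   columns, \code{mog} (the fitted interphase model).
#' @export
classify_cells <- function(records, nn_model, mog = NULL, seed = 1L) {
  cm <- classify_mitosis(nn_model, records)
  records$nn_class <- cm$class
  inter <- which(cm$class == 1L)
  if (is.null(mog)) mog <- fit_interphase_mog(records[inter, ], seed = seed)
  ph <- rep(NA_character_, nrow(records))
  ph[records$nn_class %in% 2:5] <- "M"
  if (length(inter) > 0)
    ph[inter] <- classify_interphase(mog, records[inter, ])$phase
  records$phase <- ph
  list(records = records, mog = mog)
}

# ---- model serialization -----------------------------------------------------

#' Save / load classifier models as JSON
#' @param model \code{mitosis_classifier} or \code{interphase_mog}.
#' @param path JSON file.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1]
  payload <- unclass(model)
  if (!is.null(payload$confusion))
    payload$confusion <- matrix(as.integer(payload$confusion),
                                nrow(payload$confusion))
  jsonlite::write_json(list(type = type, model = payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$model
  if (x$type == "mitosis_classifier") {
    m$par$W <- lapply(m$par$W, as.matrix)
    m$par$b <- lapply(m$par$b, as.numeric)
    m$mu <- unlist(m$mu); m$sigma <- unlist(m$sigma)
  } else if (x$type == "interphase_mog") {
    m$means <- as.matrix(m$means)
    m$covs <- if (is.array(m$covs) && length(dim(m$covs)) == 3L) {
      lapply(seq_len(dim(m$covs)[1]), function(j) m$covs[j, , ])
    } else lapply(m$covs, as.matrix)
    m$box <- as.matrix(m$box)
  }
  structure(m, class = x$type)
}
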