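# shared fixtures, built once per test session (generation is seconds, so the
# suite stays well inside its budget)

fixture_env <- new.env(parent = emptyenv())

# small interphase-only slide with all artifacts on (default spec)
small_slide <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- generate_slide(
      150, c(G1 = 0.5, S = 0.1, G2 = 0.4), confluence = 0.2, seed = 7)
  }
  fixture_env$small
}

# artifact-free twin used by identity / oracle tests
clean_slide <- function() {
  if (is.null(fixture_env$clean)) {
    fixture_env$clean <- generate_slide(
      150, c(G1 = 0.5, S = 0.1, G2 = 0.4), confluence = 0.2, seed = 7,
      artifacts = artifact_spec(background = list(enable = FALSE),
                                stripes = list(enable = FALSE),
                                gain_drift = list(enable = FALSE),
                                noise = list(shot = 0, read = 0)))
  }
  fixture_env$clean
}

# larger artifact-free slide for the correction-identity checks
clean_slide_big <- function() {
  if (is.null(fixture_env$clean_big)) {
    fixture_env$clean_big <- generate_slide(
      600, c(G1 = 0.5, S = 0.1, G2 = 0.4), confluence = 0.2, seed = 19,
      sep_frac = 1.25,
      artifacts = artifact_spec(background = list(enable = FALSE),
                                stripes = list(enable = FALSE),
                                gain_drift = list(enable = FALSE),
                                noise = list(shot = 0.3, read = 2)))
  }
  fixture_env$clean_big
}

# rasterized ellipse mask (axes in px, centred), for shape/feature oracles
ellipse_mask <- function(a, b, n = NULL, angle = 0) {
  n <- n %||% (2 * ceiling(max(a, b)) + 5)
  ctr <- (n + 1) / 2
  d <- expand.grid(r = seq_len(n), c = seq_len(n))
  u <- cos(angle) * (d$c - ctr) + sin(angle) * (d$r - ctr)
  v <- -sin(angle) * (d$c - ctr) + cos(angle) * (d$r - ctr)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("%.6g within %g of %.6g", object, tol, target))
}

# brute-force opening-by-reconstruction sequence used as the granularity oracle
brute_granularity <- function(mask, img, G) {
  se <- slidedamage:::disk_offsets(1)
  ero_one <- function(m) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      v <- Inf
      for (k in seq_len(nrow(se))) {
        rr <- r + se[k, 1]; cc <- c + se[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) v <- min(v, m[rr, cc])
      }
      out[r, c] <- v
    }
    out
  }
  rec_dil <- function(marker, limit) {
    cur <- pmin(marker, limit)
    repeat {
      nxt <- cur
      nr <- nrow(cur); nc <- ncol(cur)
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        v <- cur[r, c]
        if (r > 1) v <- max(v, cur[r - 1, c])
        if (r < nr) v <- max(v, cur[r + 1, c])
        if (c > 1) v <- max(v, cur[r, c - 1])
        if (c < nc) v <- max(v, cur[r, c + 1])
        nxt[r, c] <- min(v, limit[r, c])
      }
      if (identical(nxt, cur)) break
      cur <- nxt
    }
    cur
  }
  orig <- img * mask
  start <- mean(orig[mask])
  ero <- orig
  cur <- start
  out <- numeric(G)
  for (g in seq_len(G)) {
    ero <- ero_one(ero)
    rec <- rec_dil(ero, orig)
    nm <- mean(rec[mask])
    out[g] <- 100 * (cur - nm) / start
    cur <- nm
  }
  out
}

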