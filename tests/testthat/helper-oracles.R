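# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: the segment oracle is a literal
# exhaustive scan, and the SVM oracle solves the dual quadratic program with
# an interior-point solver and evaluates the decision function directly.

# exhaustive-scan segment oracle on an averaged-energy sequence (1-based in,
# 0-based half-open out, matching the detector's coordinate convention)
oracle_scan_segments <- function(ema, threshold, N) {
  n <- length(ema)
  sustained_supra <- function(t) {
    t + N - 1L <= n && all(ema[t:(t + N - 1L)] >= threshold)
  }
  sustained_sub <- function(t) {
    t + N - 1L <= n && all(ema[t:(t + N - 1L)] < threshold)
  }
  starts <- integer(0); ends <- integer(0)
  t <- 1L
  while (t <= n) {
    if (ema[t] >= threshold && sustained_supra(t)) {
      s <- t
      t <- t + 1L
      e <- NA_integer_
      while (t <= n) {
        if (ema[t] < threshold && sustained_sub(t)) { e <- t; break }
        t <- t + 1L
      }
      if (is.na(e)) e <- n + 1L
      starts <- c(starts, s - 1L)
      ends <- c(ends, e - 1L)
    }
    t <- t + 1L
  }
  tibble::tibble(start = starts, end = ends)
}

# a single-burst rectangular-energy fixture in raw-signal space
make_burst_signal <- function(n = 3000L, burst_start = 1000L, burst_end = 2000L,
                              burst_amp = 1, baseline_amp = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    x <- baseline_amp * sample(c(-1, 1), n, replace = TRUE)
    idx <- (burst_start + 1L):burst_end
    x[idx] <- burst_amp * sample(c(-1, 1), length(idx), replace = TRUE)
  })
  x
}

# brute-force binary SVM: solve the soft-margin dual with kernlab::ipop and
# evaluate f(x) = sum alpha_i y_i K(x_i, x) + b directly
oracle_binary_svm <- function(x, y, C, gamma) {
  stopifnot(length(unique(y)) == 2L)
  classes <- sort(unique(y))
  ysign <- ifelse(y == classes[1L], 1, -1)
  K <- exp(-gamma * as.matrix(stats::dist(x))^2)
  H <- (ysign %o% ysign) * K
  n <- length(ysign)
  sol <- kernlab::ipop(
    c = matrix(-1, n, 1), H = H,
    A = matrix(ysign, 1, n), b = 0, r = 0,
    l = matrix(0, n, 1), u = matrix(C, n, 1),
    sigf = 9, maxiter = 200
  )
  alpha <- as.numeric(kernlab::primal(sol))
  free <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  if (!length(free)) free <- which(alpha > 1e-6 * C)
  f_nob <- K %*% (alpha * ysign)
  b <- mean(ysign[free] - f_nob[free])
  list(
    alpha = alpha, b = b, classes = classes,
    predict = function(newx) {
      d2 <- outer(rowSums(newx^2), rowSums(x^2), `+`) - 2 * tcrossprod(newx, x)
      Kn <- exp(-gamma * d2)
      d <- as.numeric(Kn %*% (alpha * ysign) + b)
      ifelse(d >= 0, classes[1L], classes[2L])
    }
  )
}

# two-pass mean/deviation reference for the population SD
oracle_population_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

make_blob_dataset <- function(n_per_class = 20L, centers = list(c(0, 0), c(6, 6)),
                              sd = 0.5, labels = LETTERS[seq_along(centers)],
                              seed = 1L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(centers), function(i) {
      tibble::tibble(
        label = labels[i],
        f1 = stats::rnorm(n_per_class, centers[[i]][1L], sd),
        f2 = stats::rnorm(n_per_class, centers[[i]][2L], sd)
      )
    })
  })
  dplyr::bind_rows(rows)
}
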