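# Internal helpers: seeded evaluation, FWHM estimation, small hashing.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash).  Used to derive
# independent per-component RNG streams and to fingerprint configurations.
str_hash31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647L
  as.integer(h)
}

# Per-component seed: independent of which other components are present,
# so dropping one component leaves the others' streams untouched.
component_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 2654435761 + str_hash31(label)) %% 2147483647)
}

degrees <- function(rad) rad * 180 / pi
radians <- function(deg) deg * pi / 180

# Row-wise Euclidean norm of an n x 3 matrix.
row_norm <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) m / row_norm(m)

# FWHM of a unimodal empirical distribution, via a Gaussian fit to the
# histogram core (centre +/- ~1.2 x an initial FWHM guess).  A core fit is
# the conventional estimator for detector-resolution distributions, which
# carry non-Gaussian tails.
fwhm_from_sample <- function(x, bin_width = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 samples to estimate a FWHM")
  s0 <- min(sd(x), diff(quantile(x, c(0.25, 0.75))) / 1.349)
  if (is.null(bin_width)) bin_width <- max(s0 / 12, 1e-6)
  m0 <- median(x)
  lo <- m0 - 4 * s0
  hi <- m0 + 4 * s0
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 8) stop("degenerate sample for FWHM estimation")
  counts <- tabulate(findInterval(x, edges, rightmost.closed = FALSE),
                     nbins = length(edges))[-length(edges)]
  centers <- edges[-length(edges)] + bin_width / 2
  # core region: +/- 1.2 sigma-equivalents around the mode
  mode0 <- centers[which.max(counts)]
  core <- abs(centers - mode0) <= 2.0 * s0
  cc <- centers[core]
  cy <- counts[core]
  fit <- gauss_fit_ls(cc, cy, mu0 = mode0, sigma0 = s0, a0 = max(cy))
  .FWHM_SIGMA * fit$sigma
}

# Least-squares Gaussian fit (amplitude, mean, sigma) via optim; robust
# starting values are the caller's job.
gauss_fit_ls <- function(x, y, mu0, sigma0, a0) {
  obj <- function(p) {
    a <- p[1]; mu <- p[2]; sg <- abs(p[3])
    sum((y - a * exp(-(x - mu)^2 / (2 * sg^2)))^2)
  }
  res <- optim(c(a0, mu0, sigma0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(a = res$par[1], mu = res$par[2], sigma = abs(res$par[3]),
       value = res$value, convergence = res$convergence)
}
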