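# Progressive first-failure censoring schemes and sample generation.

#' Construct a progressive first-failure censoring scheme
#'
#' A PFFC design tests `n` groups of `k` units each and observes `m` ordered
#' first-failure times; at the `i`-th observed failure, `R[i]` of the
#' surviving groups are withdrawn, so `sum(R) = n - m`.  Either supply the
#' removal vector `R` directly or pick one of the three conventional
#' patterns: `"SC1"` removes all `n - m` groups at the first failure,
#' `"SC3"` removes them all at the last, and `"SC2"` removes them in the
#' middle (split across positions `m/2` and `m/2 + 1` for even `m`; for even
#' `m` with odd `n - m` the split is `floor`/`ceiling` with a warning, so
#' that simulation grids are not artificially restricted).
#'
#' @param n number of groups on test.
#' @param m number of observed first failures, `1 <= m <= n`.
#' @param k group size, `k >= 1` (`k = 1` reduces the design to ordinary
#'   progressive Type-II censoring).
#' @param R optional removal vector of length `m` with `sum(R) = n - m`.
#' @param kind one of `"SC1"`, `"SC2"`, `"SC3"`; ignored when `R` is given.
#' @return an object of class `"pffc_scheme"`: a list with elements `n`,
#'   `m`, `k`, `R`.
#' @examples
#' pffc_scheme(30, 15, k = 2, kind = "SC1")   # R = (15, 0, ..., 0)
#' pffc_scheme(20, 10, k = 5, R = c(2,1,1,2,1,1,1,1,0,0))
#' @export
pffc_scheme <- function(n, m, k = 1, R = NULL, kind = c("SC1", "SC2", "SC3")) {
  if (m < 1 || m > n) stop("need 1 <= m <= n", call. = FALSE)
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (is.null(R)) {
    kind <- match.arg(kind)
    R <- rep(0, m)
    nm <- n - m
    if (kind == "SC1") {
      R[1] <- nm
    } else if (kind == "SC3") {
      R[m] <- nm
    } else {
      if (m %% 2 == 0) {
        if (nm %% 2 == 1)
          warning("SC2 with even m and odd n - m: removals split ",
                  floor(nm / 2), "/", ceiling(nm / 2))
        R[m / 2] <- floor(nm / 2)
        R[m / 2 + 1] <- nm - floor(nm / 2)
      } else {
        R[(m + 1) / 2] <- nm
      }
    }
  }
  if (length(R) != m || any(R < 0) || any(R != round(R)))
    stop("'R' must be a vector of ", m, " nonnegative integers", call. = FALSE)
  if (sum(R) != n - m)
    stop("invalid scheme: sum(R) = ", sum(R), " but n - m = ", n - m,
         call. = FALSE)
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 R = as.numeric(R)),
            class = "pffc_scheme")
}

#' @export
print.pffc_scheme <- function(x, ...) {
  cat("PFFC scheme: n =", x$n, "groups of k =", x$k,
      "units, m =", x$m, "observed failures\n")
  cat("R =", paste(x$R, collapse = ", "), "\n")
  invisible(x)
}

#' Bundle observed first-failure times with their censoring scheme
#'
#' @param x nondecreasing vector of `m` nonnegative failure times.
#' @param scheme a [pffc_scheme()].
#' @return an object of class `"pffc_sample"`: a list with elements `x` and
#'   `scheme`.
#' @export
pffc_sample <- function(x, scheme) {
  if (!inherits(scheme, "pffc_scheme")) stop("'scheme' must be a pffc_scheme")
  if (length(x) != scheme$m)
    stop("expected ", scheme$m, " observations, got ", length(x))
  if (any(x < 0)) stop("failure times must be >= 0")
  if (is.unsorted(x)) stop("failure times must be nondecreasing")
  structure(list(x = as.numeric(x), scheme = scheme), class = "pffc_sample")
}

#' @export
print.pffc_sample <- function(x, ...) {
  print(x$scheme)
  cat("x =", paste(signif(x$x, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a progressively first-failure censored sample
#'
#' Draws one PFFC sample from the modified Weibull distribution by the
#' Balakrishnan-Sandhu algorithm applied to the first-failure law
#' \eqn{1 - (1 - F(x))^k}: with
#' \eqn{W_i \sim U(0,1)}, set
#' \eqn{V_i = W_i^{1/(i + R_m + \cdots + R_{m-i+1})}},
#' \eqn{U_i = 1 - V_m V_{m-1} \cdots V_{m-i+1}} (a progressive Type-II
#' uniform sample), and invert
#' \eqn{X_i = F^{-1}(1 - (1 - U_i)^{1/k})}.
#'
#' Randomness comes from R's global generator, so a fixed `set.seed` gives a
#' bit-identical sample.
#'
#' @param scheme a [pffc_scheme()].
#' @inheritParams mwd
#' @return a [pffc_sample()] of the scheme's `m` ordered times.
#' @examples
#' sch <- pffc_scheme(30, 15, k = 2, kind = "SC1")
#' set.seed(1)
#' rpffc(sch, 1, 0.1, 2)
#' @export
rpffc <- function(scheme, alpha, beta, lambda) {
  check_mwd_params(alpha, beta, lambda)
  m <- scheme$m; R <- scheme$R; k <- scheme$k
  U <- .rprog_unif(m, R)
  x <- qmwd(1 - (1 - U)^(1 / k), alpha, beta, lambda)
  pffc_sample(sort(x), scheme)
}

# progressive Type-II uniform order statistics (Balakrishnan-Sandhu)
.rprog_unif <- function(m, R) {
  W <- runif(m)
  # gamma_i = i + R_m + ... + R_{m-i+1}
  gam <- seq_len(m) + cumsum(rev(R))
  V <- W^(1 / gam)
  # U_i = 1 - V_m V_{m-1} ... V_{m-i+1}
  U <- 1 - cumprod(rev(V))
  U
}

#' Read and write PFFC samples
#'
#' `write_pffc` serializes a sample as a plain CSV (columns `index`, `x`,
#' `R`) preceded by a single comment line holding the design header as JSON
#' (`{"n": ..., "m": ..., "k": ...}`).  `read_pffc` parses the file and
#' re-validates the scheme invariant `sum(R) = n - m`.
#'
#' @param sample a [pffc_sample()].
#' @param file path to a CSV file.
#' @return `read_pffc` returns a [pffc_sample()]; `write_pffc` returns
#'   `file` invisibly.
#' @export
write_pffc <- function(sample, file) {
  hdr <- jsonlite::toJSON(list(n = sample$scheme$n, m = sample$scheme$m,
                               k = sample$scheme$k), auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.csv(data.frame(index = seq_along(sample$x), x = sample$x,
                       R = sample$scheme$R),
            con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pffc
#' @export
read_pffc <- function(file) {
  first <- readLines(file, n = 1L)
  if (!startsWith(first, "# "))
    stop("not a PFFC sample file (missing JSON header line)")
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  d <- read.csv(file, comment.char = "#")
  sch <- pffc_scheme(hdr$n, hdr$m, hdr$k, R = d$R)
  pffc_sample(d$x, sch)
}
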