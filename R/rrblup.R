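#' Fit a ridge-regression BLUP genomic prediction model
#'
#' The mixed model `y = 1 b + Z u + e` with i.i.d. marker effects
#' `u ~ N(0, var_u I)` and residuals `e ~ N(0, var_e I)`: every marker
#' effect is shrunk equally, the "common marker variance" assumption of
#' ridge-regression BLUP. Markers are centred by their training means (no
#' unit-variance scaling). When `lambda` (the ridge ratio
#' `var_e / var_u`) is not supplied it is estimated by REML: the kernel
#' `K = Zc Zc'` is eigendecomposed once and the profiled restricted
#' log-likelihood is maximised over `log(lambda)` on \[1e-6, 1e6\] by bounded
#' scalar search; endpoint optima are flagged as boundary fits. The
#' intercept is the generalised-least-squares estimate at the fitted ratio,
#' and marker effects are `u = Zc' (Zc Zc' + lambda I)^-1 (y - b 1)`.
#'
#' @param Z accessions x markers dosage matrix (complete, column names are
#'   marker ids).
#' @param y response vector (typically trial-BLUP genetic values),
#'   length `nrow(Z)`, at least 3.
#' @param lambda optional fixed ridge ratio `var_e / var_u`.
#' @return An object of class `rrblup`: `b_hat`, `u_hat` (named per-marker
#'   effects), `lambda`, `var_u`, `var_e`, `marker_ids`,
#'   `train_mean_dosage`, and `boundary` (logical).
#' @export
fit_rrblup <- function(Z, y, lambda = NULL) {
  Z <- as.matrix(Z)
  if (anyNA(Z) || anyNA(y)) stop("Z and y must be complete")
  n <- nrow(Z)
  if (n < 3) stop("need at least 3 accessions")
  stopifnot(length(y) == n)
  if (is.null(colnames(Z))) colnames(Z) <- sprintf("M%05d", seq_len(ncol(Z)))
  mu_m <- colMeans(Z)
  Zc <- sweep(Z, 2, mu_m)

  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    # constant response: no genetic signal, infinite shrinkage
    warning("response is constant; returning a zero-effect model")
    return(structure(list(b_hat = mean(y),
                          u_hat = stats::setNames(numeric(ncol(Z)), colnames(Z)),
                          lambda = Inf, var_u = 0, var_e = 0,
                          marker_ids = colnames(Z), train_mean_dosage = mu_m,
                          boundary = TRUE), class = "rrblup"))
  }

  K <- tcrossprod(Zc)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  gls_fit <- function(lam) {
    w <- 1 / (d + lam)
    b <- sum(w * xt * yt) / sum(w * xt^2)
    r <- yt - xt * b
    list(b = b, rss_w = sum(w * r^2), w = w, r = r)
  }

  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- profile_reml_ratio(d, xt, yt, log(1e-6), log(1e6))
    lambda <- opt$ratio
    if (opt$at_bound) {
      boundary <- TRUE
      warning("REML ratio estimate at the search boundary (lambda = ",
              signif(lambda, 3), ")")
    }
  }
  f <- gls_fit(lambda)
  var_u <- f$rss_w / (n - 1)
  var_e <- lambda * var_u
  u_hat <- drop(crossprod(Zc, U %*% (f$w * f$r)))
  structure(list(b_hat = f$b, u_hat = stats::setNames(u_hat, colnames(Z)),
                 lambda = lambda, var_u = var_u, var_e = var_e,
                 marker_ids = colnames(Z), train_mean_dosage = mu_m,
                 boundary = boundary),
            class = "rrblup")
}

#' Predict genomic values for new accessions
#'
#' `b_hat + (Z_new - train_mean_dosage) u_hat`. Columns of `Z_new` must
#' match the training marker ids exactly (no silent reordering).
#'
#' @param object a fitted [fit_rrblup()] model.
#' @param Z_new accessions x markers dosage matrix with the training marker
#'   columns.
#' @param ... ignored.
#' @return Numeric vector of predicted genomic values.
#' @export
predict.rrblup <- function(object, Z_new, ...) {
  Z_new <- as.matrix(Z_new)
  if (!is.null(colnames(Z_new)) && !identical(colnames(Z_new), object$marker_ids))
    stop("marker columns of Z_new do not match the training markers")
  if (ncol(Z_new) != length(object$marker_ids))
    stop("marker columns of Z_new do not match the training markers")
  drop(object$b_hat + sweep(Z_new, 2, object$train_mean_dosage) %*% object$u_hat)
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("<rrblup> %d markers; b=%.4g lambda=%.4g var_u=%.4g var_e=%.4g%s\n",
              length(x$u_hat), x$b_hat, x$lambda, x$var_u, x$var_e,
              if (x$boundary) " (boundary fit)" else ""))
  invisible(x)
}

#' Genomic (VanRaden-style) kinship matrix
#'
#' `K = Zc Zc' / m` with `Zc` the dosage matrix centred by `center`
#' (training-set column means by default). Symmetric and positive
#' semi-definite; the kernel form dual to the marker-effect rrBLUP model.
#'
#' @param Z accessions x markers dosage matrix (complete).
#' @param center optional centring vector (length `ncol(Z)`); defaults to
#'   `colMeans(Z)`. Supplying training means keeps train/test kinship
#'   blocks consistent in cross-validation.
#' @return An accessions x accessions kinship matrix.
#' @export
kinship <- function(Z, center = NULL) {
  Z <- as.matrix(Z)
  if (anyNA(Z)) stop("Z must be complete")
  if (is.null(center)) center <- colMeans(Z)
  Zc <- sweep(Z, 2, center)
  tcrossprod(Zc) / ncol(Z)
}

#' Genomic heritability implied by an rrBLUP fit
#'
#' `var_u * c / (var_u * c + var_e)` with `c` the mean diagonal of
#' `Zc Zc'`, i.e. the genetic variance carried by the observed markers
#' relative to the total.
#'
#' @param model a fitted [fit_rrblup()] model.
#' @param Z the training dosage matrix the model was fitted on.
#' @return A value in \[0, 1\].
#' @export
genomic_h2 <- function(model, Z) {
  stopifnot(inherits(model, "rrblup"))
  Zc <- sweep(as.matrix(Z), 2, model$train_mean_dosage)
  cc <- mean(rowSums(Zc^2))
  vg <- model$var_u * cc
  if (vg + model$var_e <= 0) return(0)
  vg / (vg + model$var_e)
}

#' Serialise / load an rrBLUP model as delimited text
#'
#' Header lines (`#b_hat`, `#lambda`, `#var_u`, `#var_e`) followed by a
#' three-column table (`marker_id`, `effect`, `train_mean_dosage`).
#'
#' @param model a fitted [fit_rrblup()] model.
#' @param path output path.
#' @return `path` invisibly; `read_rrblup()` returns the model.
#' @export
write_rrblup <- function(model, path) {
  stopifnot(inherits(model, "rrblup"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#%s=%.17g", c("b_hat", "lambda", "var_u", "var_e"),
                     c(model$b_hat, model$lambda, model$var_u, model$var_e)), con)
  writeLines("marker_id\teffect\ttrain_mean_dosage", con)
  writeLines(sprintf("%s\t%.17g\t%.17g", model$marker_ids, model$u_hat,
                     model$train_mean_dosage), con)
  invisible(path)
}

#' @rdname write_rrblup
#' @export
read_rrblup <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) as.numeric(sub(paste0("#", key, "="), "", hdr[startsWith(hdr, paste0("#", key, "="))]))
  tab <- utils::read.delim(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"))
  structure(list(b_hat = val("b_hat"),
                 u_hat = stats::setNames(tab$effect, tab$marker_id),
                 lambda = val("lambda"), var_u = val("var_u"), var_e = val("var_e"),
                 marker_ids = tab$marker_id,
                 train_mean_dosage = stats::setNames(tab$train_mean_dosage, tab$marker_id),
                 boundary = FALSE), class = "rrblup")
}
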