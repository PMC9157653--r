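#' Fit a multivariate kinship-based mixed model
#'
#' Multi-trait genomic prediction: `vec(Y) = (I (x) 1) B + g + e` with
#' `cov(g) = Sigma_g (x) K` and `cov(e) = Sigma_e (x) I`, the multivariate
#' extension of the univariate kinship (GBLUP) model in which the
#' trait-by-trait genetic covariance enters the random-effect variance.
#' `K` is eigendecomposed once; in the rotated basis rows are independent
#' with covariance `d_i Sigma_g + Sigma_e`, and `Sigma_g`, `Sigma_e` are
#' estimated by EM-REML (expected cross-products of BLUPs and residuals,
#' with the fixed-effect correction, so the restricted likelihood is
#' non-decreasing). Convergence: maximum relative change in either
#' covariance below `tol` (default 1e-6), at most `max_iter` iterations.
#'
#' With a single trait the same restricted likelihood is maximised directly
#' by profiled 1-D search (as in [fit_rrblup()]), to which the model reduces
#' exactly.
#'
#' @param K training kinship matrix (n x n, PSD), e.g. from [kinship()].
#' @param Y accessions x traits matrix of responses (complete).
#' @param max_iter maximum EM iterations.
#' @param tol relative convergence tolerance.
#' @return An object of class `multitrait_model`: `trait_names`, `B_hat`
#'   (t intercepts), `Sigma_g`, `Sigma_e`, `blup_matrix` (n x t genetic
#'   BLUPs), `kinship_ref`, `accession_ids`, `loglik` trace, `converged`.
#' @export
fit_multitrait <- function(K, Y, max_iter = 500, tol = 1e-6) {
  K <- as.matrix(K); Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (anyNA(Y) || anyNA(K)) stop("K and Y must be complete")
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("trait_%d", seq_len(t))
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Yt <- crossprod(U, Y)
  xt <- drop(crossprod(U, rep(1, n)))

  if (t == 1L) {
    fit <- kernel_reml_1d(d, xt, drop(Yt))
    ghat_rot <- d * fit$w * (drop(Yt) - xt * fit$b)
    blup <- U %*% (ghat_rot)
    out <- list(trait_names = colnames(Y), B_hat = fit$b,
                Sigma_g = matrix(fit$var_g, 1, 1,
                                 dimnames = list(colnames(Y), colnames(Y))),
                Sigma_e = matrix(fit$var_e, 1, 1,
                                 dimnames = list(colnames(Y), colnames(Y))),
                blup_matrix = matrix(blup, n, 1,
                                     dimnames = list(rownames(Y), colnames(Y))),
                kinship_ref = K, accession_ids = rownames(Y),
                loglik = fit$loglik, converged = TRUE)
    return(structure(out, class = "multitrait_model"))
  }

  Sg <- Se <- stats::cov(Y) / 2
  Sg <- ridge_if_singular(Sg); Se <- ridge_if_singular(Se)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Wlist <- vector("list", n)
    S <- matrix(0, t, t); rhs <- numeric(t)
    logdetV <- 0
    for (i in seq_len(n)) {
      Vi <- d[i] * Sg + Se
      Wi <- solve(Vi)
      Wlist[[i]] <- Wi
      S <- S + xt[i]^2 * Wi
      rhs <- rhs + xt[i] * drop(Wi %*% Yt[i, ])
      logdetV <- logdetV + as.numeric(determinant(Vi, logarithm = TRUE)$modulus)
    }
    Sinv <- solve(S)
    B <- drop(Sinv %*% rhs)
    Ag <- matrix(0, t, t); Ae <- matrix(0, t, t)
    quad <- 0
    for (i in seq_len(n)) {
      Wi <- Wlist[[i]]
      ri <- Yt[i, ] - xt[i] * B
      Pri <- drop(Wi %*% ri)
      Pii <- Wi - xt[i]^2 * (Wi %*% Sinv %*% Wi)   # diagonal block of the REML projector
      Ag <- Ag + d[i] * (tcrossprod(Pri) - Pii)
      Ae <- Ae + tcrossprod(Pri) - Pii
      quad <- quad + sum(ri * Pri)
    }
    ll <- -0.5 * (logdetV + as.numeric(determinant(S, logarithm = TRUE)$modulus) + quad)
    ll_trace <- c(ll_trace, ll)
    Sg_new <- Sg + (Sg %*% Ag %*% Sg) / n
    Se_new <- Se + (Se %*% Ae %*% Se) / n
    Sg_new <- ridge_if_singular((Sg_new + t(Sg_new)) / 2)
    Se_new <- ridge_if_singular((Se_new + t(Se_new)) / 2)
    scale <- max(abs(c(Sg, Se)))
    delta <- max(abs(c(Sg_new - Sg, Se_new - Se))) / max(scale, 1e-12)
    Sg <- Sg_new; Se <- Se_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("multivariate EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")

  # BLUPs at the converged covariances
  Ghat_rot <- matrix(0, n, t)
  S <- matrix(0, t, t); rhs <- numeric(t)
  Wlist <- vector("list", n)
  for (i in seq_len(n)) {
    Wi <- solve(d[i] * Sg + Se)
    Wlist[[i]] <- Wi
    S <- S + xt[i]^2 * Wi
    rhs <- rhs + xt[i] * drop(Wi %*% Yt[i, ])
  }
  B <- drop(solve(S) %*% rhs)
  for (i in seq_len(n)) {
    ri <- Yt[i, ] - xt[i] * B
    Ghat_rot[i, ] <- d[i] * drop(Sg %*% Wlist[[i]] %*% ri)
  }
  blup <- U %*% Ghat_rot
  dimnames(blup) <- list(rownames(Y), colnames(Y))
  names(B) <- colnames(Y)
  dimnames(Sg) <- dimnames(Se) <- list(colnames(Y), colnames(Y))
  structure(list(trait_names = colnames(Y), B_hat = B, Sigma_g = Sg,
                 Sigma_e = Se, blup_matrix = blup, kinship_ref = K,
                 accession_ids = rownames(Y), loglik = ll_trace,
                 converged = converged),
            class = "multitrait_model")
}

# internal: maximise the profiled restricted likelihood of V ~ K + ratio*I
# over log(ratio). Brent search first, then bisection on the analytic
# derivative (envelope theorem for the GLS intercept) to machine precision,
# so the marker-form and kernel-form solvers agree to ~1e-12 on the optimum.
profile_reml_ratio <- function(d, xt, yt, lower, upper) {
  n <- length(yt)
  gls <- function(ratio) {
    w <- 1 / (d + ratio)
    b <- sum(w * xt * yt) / sum(w * xt^2)
    r <- yt - xt * b
    list(b = b, w = w, r = r, rss_w = sum(w * r^2))
  }
  neg2ll <- function(logratio) {
    f <- gls(exp(logratio))
    (n - 1) * log(f$rss_w) + sum(log(d + exp(logratio))) + log(sum(f$w * xt^2))
  }
  # d/dratio of the profiled deviance
  dscore <- function(ratio) {
    f <- gls(ratio)
    w <- f$w
    -(n - 1) * sum(w^2 * f$r^2) / f$rss_w + sum(w) -
      sum(w^2 * xt^2) / sum(w * xt^2)
  }
  opt <- stats::optimize(neg2ll, interval = c(lower, upper), tol = 1e-9)
  lo <- max(lower, opt$minimum - 1e-4); hi <- min(upper, opt$minimum + 1e-4)
  slo <- dscore(exp(lo)); shi <- dscore(exp(hi))
  if (slo < 0 && shi > 0) {
    for (it in seq_len(100)) {
      mid <- (lo + hi) / 2
      if (dscore(exp(mid)) < 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-14) break
    }
    opt$minimum <- (lo + hi) / 2
    opt$objective <- neg2ll(opt$minimum)
  }
  ratio <- exp(opt$minimum)
  f <- gls(ratio)
  list(ratio = ratio, b = f$b, w = f$w, r = f$r, rss_w = f$rss_w,
       objective = opt$objective,
       at_bound = opt$minimum < lower + 1e-6 || opt$minimum > upper - 1e-6)
}

# internal: profiled REML in the kernel parameterization (V = vg*K + ve*I),
# returning variance components on the kinship scale
kernel_reml_1d <- function(d, xt, yt) {
  n <- length(yt)
  opt <- profile_reml_ratio(d, xt, yt, log(1e-8), log(1e8))
  var_g <- opt$rss_w / (n - 1)
  list(b = opt$b, w = opt$w, var_g = var_g, var_e = opt$ratio * var_g,
       delta = opt$ratio, loglik = -0.5 * opt$objective)
}

ridge_if_singular <- function(S, eps = 1e-8) {
  t <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eps * sum(diag(S)) / t) {
    warning("near-singular covariance estimate ridge-stabilised")
    S <- S + diag(eps * sum(diag(S)) / t, t)
  }
  S
}

#' Predict a multi-trait model for new accessions
#'
#' Conditional genetic prediction from the training BLUPs:
#' `G_test = K_cross K_train^+ G_train` applied per trait (the genetic
#' covariance factorises as `Sigma_g (x) K`, so the across-accession
#' regression is trait-wise), plus the trait intercepts.
#'
#' @param object a fitted [fit_multitrait()] model.
#' @param K_cross test x train kinship block, built on the combined
#'   accession set with the same centring as the training kinship.
#' @param ... ignored.
#' @return A test x traits matrix of predictions.
#' @export
predict.multitrait_model <- function(object, K_cross, ...) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != nrow(object$kinship_ref))
    stop("K_cross must have one column per training accession")
  eig <- eigen(object$kinship_ref, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  Kinv <- eig$vectors[, pos, drop = FALSE] %*%
    (t(eig$vectors[, pos, drop = FALSE]) / eig$values[pos])
  pred <- K_cross %*% Kinv %*% object$blup_matrix
  sweep(pred, 2, object$B_hat, "+")
}

#' @export
print.multitrait_model <- function(x, ...) {
  cat(sprintf("<multitrait_model> %d traits x %d accessions (%s, %d EM iterations)\n",
              length(x$trait_names), nrow(x$blup_matrix),
              if (x$converged) "converged" else "NOT converged", length(x$loglik)))
  cat("  genetic correlations:\n")
  print(round(stats::cov2cor(x$Sigma_g), 3))
  invisible(x)
}

#' Rv coefficient between two multi-column matrices
#'
#' The matrix correlation
#' `trace(X X' Y Y') / sqrt(trace((X X')^2) trace((Y Y')^2))` on
#' column-centred matrices; 1 when the two configurations agree up to
#' rotation/scaling, near 0 for unrelated configurations. Used to score a
#' multi-trait prediction matrix against the observed trait matrix as a
#' whole.
#'
#' @param Xm,Ym n x p and n x q numeric matrices (rows paired).
#' @return A value in \[0, 1\].
#' @export
rv_coefficient <- function(Xm, Ym) {
  Xm <- scale(as.matrix(Xm), center = TRUE, scale = FALSE)
  Ym <- scale(as.matrix(Ym), center = TRUE, scale = FALSE)
  stopifnot(nrow(Xm) == nrow(Ym))
  if (sum(Xm^2) == 0 || sum(Ym^2) == 0) stop("Rv undefined for a zero matrix")
  num <- sum(crossprod(Xm, Ym)^2)
  den <- sqrt(sum(crossprod(Xm)^2) * sum(crossprod(Ym)^2))
  num / den
}

#' Serialise / load a multi-trait model as delimited text
#'
#' Writes `<path>.sigma` (stacked `Sigma_g` and `Sigma_e`, labelled rows)
#' and `<path>.blup` (accession x trait BLUP matrix plus intercept row).
#'
#' @param model a fitted [fit_multitrait()] model.
#' @param path base output path.
#' @return `path`, invisibly.
#' @export
write_multitrait <- function(model, path) {
  stopifnot(inherits(model, "multitrait_model"))
  sig <- rbind(data.frame(component = "Sigma_g", trait = model$trait_names,
                          model$Sigma_g, check.names = FALSE),
               data.frame(component = "Sigma_e", trait = model$trait_names,
                          model$Sigma_e, check.names = FALSE))
  readr::write_tsv(tibble::as_tibble(sig), paste0(path, ".sigma"))
  blup <- tibble::as_tibble(model$blup_matrix)
  blup <- dplyr::bind_cols(
    tibble::tibble(accession_id = c("(intercept)", model$accession_ids %||%
                                      as.character(seq_len(nrow(model$blup_matrix))))[-1]),
    blup)
  hdr <- tibble::as_tibble(matrix(model$B_hat, 1,
                                  dimnames = list(NULL, model$trait_names)))
  blup <- dplyr::bind_rows(dplyr::bind_cols(tibble::tibble(accession_id = "(intercept)"), hdr), blup)
  readr::write_tsv(blup, paste0(path, ".blup"))
  invisible(path)
}
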