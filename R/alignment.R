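#' Select the reference configuration for Procrustes alignment
#'
#' The latent positions are identified only up to translation, rotation and
#' reflection, so posterior draws must be matched to a common reference
#' before averaging.  The reference is the retained draw (pooled over
#' chains) with the highest joint log-posterior; ties go to the earliest
#' chain/iteration.
#'
#' @param fit an `lsirt_fit` from [fit_lsirm()].
#' @return list with `configuration` (the stacked (P+I) x K matrix of person
#'   positions over item positions), `chain`, `iter` and `log_post`.
#' @export
select_reference <- function(fit) {
  if (fit$model != "lsirm") stop("reference selection needs latent positions")
  lp <- lapply(fit$chains, function(ch) ch$log_post)
  if (!length(lp) || !length(lp[[1]])) stop("no retained draws")
  best_chain <- 1L; best_iter <- 1L; best <- -Inf
  for (ch in seq_along(lp)) {
    j <- which.max(lp[[ch]])
    if (lp[[ch]][j] > best) {  # strict: ties keep the earliest
      best <- lp[[ch]][j]; best_chain <- ch; best_iter <- j
    }
  }
  cfg <- rbind(fit$chains[[best_chain]]$xi[, , best_iter],
               fit$chains[[best_chain]]$zeta[, , best_iter])
  list(configuration = cfg, chain = best_chain, iter = best_iter,
       log_post = best)
}

#' Procrustes-match one configuration to a reference
#'
#' Finds the rigid transform (translation plus orthogonal matrix; rotations
#' AND reflections, no scaling) of `x` minimizing the Frobenius distance to
#' `ref`, and returns the transformed configuration.  All pairwise distances
#' within `x` are preserved exactly.
#'
#' @param x,ref numeric matrices of identical dimension.
#' @return the transformed `x`.
#' @export
procrustes_transform <- function(x, ref) {
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (!all(dim(x) == dim(ref))) stop("configurations must have equal shape")
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx)
  rc <- sweep(ref, 2, cr)
  if (all(abs(xc) < 1e-300)) {
    # degenerate: all rows identical; translation-only match
    return(sweep(xc, 2, cr, "+"))
  }
  # minimize ||xc %*% R - rc||_F over orthogonal R: R = U V' from
  # svd(t(xc) %*% rc) = U D V'
  sv <- svd(crossprod(xc, rc))
  R <- sv$u %*% t(sv$v)
  sweep(xc %*% R, 2, cr, "+")
}

#' Align all posterior position draws and form point estimates
#'
#' Every retained draw's stacked person/item configuration is
#' Procrustes-matched to the highest-posterior reference draw; the aligned
#' draws are then averaged element-wise to give the position point estimates
#' \eqn{\hat\xi_p} and \eqn{\hat\zeta_i}.  Abilities, intercepts and the
#' distance weight are untouched by alignment.
#'
#' @param fit an `lsirt_fit` from [fit_lsirm()].
#' @return An object of class `lsirt_aligned`: `xi` (P x K posterior-mean
#'   person positions), `zeta` (I x K item positions), aligned draw arrays
#'   `xi_draws`, `zeta_draws` (pooled over chains), `reference` info and the
#'   id vectors.
#' @export
align_posterior <- function(fit) {
  ref <- select_reference(fit)
  P <- length(fit$response$person_ids)
  I <- length(fit$response$item_ids)
  K <- fit$config$K
  n_tot <- sum(vapply(fit$chains, function(ch) dim(ch$xi)[3], 0))
  xi_dr <- array(NA_real_, c(P, K, n_tot))
  zeta_dr <- array(NA_real_, c(I, K, n_tot))
  r <- 0L
  for (ch in fit$chains) {
    for (j in seq_len(dim(ch$xi)[3])) {
      r <- r + 1L
      al <- procrustes_transform(rbind(ch$xi[, , j], ch$zeta[, , j]),
                                 ref$configuration)
      xi_dr[, , r] <- al[seq_len(P), , drop = FALSE]
      zeta_dr[, , r] <- al[P + seq_len(I), , drop = FALSE]
    }
  }
  xi_hat <- apply(xi_dr, c(1, 2), mean)
  zeta_hat <- apply(zeta_dr, c(1, 2), mean)
  rownames(xi_hat) <- fit$response$person_ids
  rownames(zeta_hat) <- fit$response$item_ids
  structure(
    list(xi = xi_hat, zeta = zeta_hat,
         xi_draws = xi_dr, zeta_draws = zeta_dr,
         reference = ref,
         person_ids = fit$response$person_ids,
         item_ids = fit$response$item_ids),
    class = "lsirt_aligned")
}

#' @export
print.lsirt_aligned <- function(x, ...) {
  cat(sprintf(
    "<lsirt_aligned> %d person + %d item positions in %d dims (%d draws)\n",
    nrow(x$xi), nrow(x$zeta), ncol(x$xi), dim(x$xi_draws)[3]))
  invisible(x)
}
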