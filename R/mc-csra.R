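# Multiple-coefficient class-specific residual attention (MC-CSRA) head.
#
# Scores are `(GAP(x) %*% W_fc + b) %*% Coef`: global average pooling, a
# fully-connected layer producing per-label base scores, then a trainable
# n_classes x n_classes coefficient matrix whose column k mixes the base
# scores into the final score for label k. With Coef = I the head is exactly
# the plain GAP + linear head, which makes the ablation continuous and the
# equivalence testable; trained off identity, the off-diagonal entries
# express learned label-to-label couplings.

#' Coefficient mixing layer
#'
#' Right-multiplies per-label base scores by a trainable square coefficient
#' matrix (column `k` produces the final score of label `k`).
#'
#' @param n_classes Label count.
#' @param init `"identity"` (exact baseline equivalence) or
#'   `"identity_noise"` (identity plus small Gaussian noise, sd `noise_sd`,
#'   drawn from the current RNG stream).
#' @param noise_sd Noise scale for `"identity_noise"`.
#' @return A module.
#' @export
nn_coef <- function(n_classes, init = c("identity", "identity_noise"),
                    noise_sd = 0.01) {
  init <- match.arg(init)
  coef <- diag(n_classes)
  if (init == "identity_noise") {
    coef <- coef + matrix(stats::rnorm(n_classes^2, sd = noise_sd),
                          n_classes, n_classes)
  }
  new_module("nn_coef", params = list(coef = coef), n_classes = n_classes)
}

#' @export
nn_forward.nn_coef <- function(mod, x) {
  mod$cache <- list(x = x)
  x %*% mod$params$coef
}

#' @export
nn_backward.nn_coef <- function(mod, gy) {
  mod$grads$coef <- mod$grads$coef + crossprod(mod$cache$x, gy)
  gy %*% t(mod$params$coef)
}

#' @export
nn_trace.nn_coef <- function(mod, shape) {
  list(shape = mod$n_classes, macs = mod$n_classes^2)
}

#' MC-CSRA scoring head
#'
#' @param in_ch Feature-map channel count.
#' @param n_classes Label count.
#' @param init Coefficient initialisation, see [nn_coef()].
#' @param noise_sd Noise scale for `"identity_noise"` initialisation.
#' @return A module mapping a `H x W x C x N` feature map to `N x n_classes`
#'   logits.
#' @export
nn_mc_csra <- function(in_ch, n_classes, init = "identity_noise",
                       noise_sd = 0.01) {
  nn_sequential(
    nn_gap(),
    nn_linear(in_ch, n_classes),
    nn_coef(n_classes, init, noise_sd)
  )
}

#' Plain pooled-linear scoring head (GAP + fully-connected)
#' @param in_ch Feature-map channel count.
#' @param n_classes Label count.
#' @return A module.
#' @export
nn_gap_linear_head <- function(in_ch, n_classes) {
  nn_sequential(nn_gap(), nn_linear(in_ch, n_classes))
}

# Locate the coefficient sub-module inside a model tree (NULL if absent).
find_coef_module <- function(mod) {
  if (inherits(mod, "nn_coef")) return(mod)
  for (ch in mod$children) {
    r <- find_coef_module(ch)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Report the learned label-coupling coefficients
#'
#' Extracts the MC-CSRA coefficient matrix from a model, labels its rows
#' (source label whose base score is mixed in) and columns (target label
#' being scored), and summarises the deviation from the identity.
#'
#' @param model A model containing an MC-CSRA head.
#' @param labels Label names (defaults to [complication_labels()]).
#' @return A list with `coef` (named matrix), `deviation` (Frobenius norm of
#'   `Coef - I`) and `off_diagonal` (data frame of off-diagonal entries
#'   sorted by absolute magnitude).
#' @export
correlation_report <- function(model, labels = complication_labels()) {
  if (!inherits(model, "nn_module")) model <- model_module(model)
  cm <- find_coef_module(model)
  if (is.null(cm)) stop_thanet("model has no MC-CSRA coefficient block")
  coef <- cm$params$coef
  if (nrow(coef) != length(labels)) {
    labels <- paste0("class", seq_len(nrow(coef)))
  }
  dimnames(coef) <- list(source = labels, target = labels)
  offd <- which(row(coef) != col(coef), arr.ind = TRUE)
  off <- data.frame(
    source = labels[offd[, 1]],
    target = labels[offd[, 2]],
    coef = coef[offd],
    stringsAsFactors = FALSE
  )
  off <- off[order(-abs(off$coef)), ]
  rownames(off) <- NULL
  list(coef = coef,
       deviation = sqrt(sum((coef - diag(nrow(coef)))^2)),
       off_diagonal = off)
}

#' Write the coefficient matrix to CSV
#' @param model Model with an MC-CSRA head.
#' @param path Output CSV path.
#' @param labels Label names.
#' @return `path`, invisibly.
#' @export
export_coef_csv <- function(model, path, labels = complication_labels()) {
  rep <- correlation_report(model, labels)
  utils::write.csv(as.data.frame(rep$coef), path, row.names = TRUE)
  invisible(path)
}
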