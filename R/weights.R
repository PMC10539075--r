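#' Impute a disease label and analysis weight from an affection probability
#'
#' Converts an estimated affection probability \eqn{p} into the imputed
#' case/control label and the analysis weight used by the weighted association
#' test:
#' \deqn{y = \mathbf{1}\{p \ge 0.5\}, \qquad
#'       w = \begin{cases} p & p \ge 0.5 \\ 1 - p & p < 0.5, \end{cases}}
#' so that \eqn{w = \max(p, 1-p) \in [0.5, 1]} is the confidence of the
#' classification.  Note the tie at \eqn{p = 0.5} is deliberately coded as a
#' case (the rule is \eqn{\ge}); on balanced data this choice is visible, so it
#' is stated here prominently.
#'
#' Labeled subjects (clinically diagnosed cases and controls) never go through
#' this rule: their probability is fixed at 1 or 0 and their weight at 1.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return a data frame with columns `y` (integer 0/1) and `w` (numeric).
#' @examples
#' impute_and_weight(c(0.9, 1, 0.5, 0.2))
#' @export
impute_and_weight <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("'p' must be probabilities in [0, 1]")
  y <- as.integer(p >= 0.5)
  data.frame(y = y, w = ifelse(y == 1L, p, 1 - p))
}

#' Per-subject status table for a partially labeled cohort
#'
#' Builds the canonical per-subject table of disease code, affection
#' probability and analysis weight from clinical labels and (for unlabeled
#' subjects) predicted probabilities, enforcing the invariants:
#' cases have \eqn{(y, p, w) = (1, 1, 1)}, controls \eqn{(0, 0, 1)}, and
#' missing-status subjects get \eqn{y, w} from [impute_and_weight()].
#'
#' @param label character/factor vector with values `"case"`, `"control"`,
#'   `"missing"`.
#' @param p affection probabilities; required (non-`NA`) exactly for the
#'   `"missing"` subjects, ignored for labeled subjects.
#' @return data frame with columns `label`, `y`, `p`, `w`.
#' @export
subject_status <- function(label, p = NULL) {
  label <- as.character(label)
  ok <- label %in% c("case", "control", "missing")
  if (!all(ok)) stop("unknown label(s): ", paste(unique(label[!ok]), collapse = ", "))
  n <- length(label)
  if (is.null(p)) p <- rep(NA_real_, n)
  if (length(p) != n) stop("'p' must have one entry per subject")
  out <- data.frame(label = label, y = NA_integer_, p = as.numeric(p),
                    w = NA_real_)
  out$p[label == "case"] <- 1
  out$p[label == "control"] <- 0
  out$y[label == "case"] <- 1L
  out$y[label == "control"] <- 0L
  out$w[label != "missing"] <- 1
  m <- label == "missing"
  if (any(m)) {
    if (anyNA(out$p[m]))
      stop("affection probability 'p' required for every 'missing' subject")
    iw <- impute_and_weight(out$p[m])
    out$y[m] <- iw$y
    out$w[m] <- iw$w
  }
  out
}

#' Assemble an analysis cohort
#'
#' Bundles the per-subject status table with the covariate design and genotype
#' column(s) used by the association tests, checking row alignment.
#'
#' @param status a data frame from [subject_status()].
#' @param Z covariate matrix/data.frame (an intercept column is added if
#'   absent).
#' @param G genotype vector or matrix (additive dosage of the minor allele).
#' @return an object of class `"wip_cohort"`.
#' @export
wip_cohort <- function(status, Z, G) {
  Z <- as.matrix(Z)
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
  n <- nrow(status)
  if (nrow(Z) != n || nrow(G) != n) stop("rows of status, Z and G must align")
  if (!any(apply(Z, 2, function(x) all(x == 1))))
    Z <- cbind(`(Intercept)` = 1, Z)
  structure(list(status = status, Z = Z, G = G, n = n), class = "wip_cohort")
}

#' @export
print.wip_cohort <- function(x, ...) {
  tab <- table(factor(x$status$label, c("case", "control", "missing")))
  cat("wip_cohort:", x$n, "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("covariates:", paste(colnames(x$Z), collapse = ", "),
      "| genotype columns:", ncol(x$G), "\n")
  invisible(x)
}

#' Fit one analysis method on a cohort
#'
#' The three analysis methods are the same estimator under different
#' (subset, weight) inputs, all dispatched through [wgee_fit()]:
#' \describe{
#'   \item{`"lr"`}{labeled subjects only, unit weights — ordinary logistic
#'     regression.}
#'   \item{`"ip"`}{labeled plus imputed subjects, unit weights.}
#'   \item{`"wip"`}{labeled plus imputed subjects, weights
#'     \eqn{\max(p, 1-p)}.}
#' }
#'
#' @param cohort a `"wip_cohort"`.
#' @param method `"lr"`, `"ip"` or `"wip"`.
#' @param include_genotype fit with the genotype column(s) (default) or the
#'   covariate-only null model.
#' @param ... passed to [wgee_fit()].
#' @return a `"wgee"` fit.
#' @export
fit_method <- function(cohort, method = c("wip", "ip", "lr"),
                       include_genotype = TRUE, ...) {
  method <- match.arg(method)
  st <- cohort$status
  idx <- if (method == "lr") which(st$label != "missing") else seq_len(cohort$n)
  w <- if (method == "wip") st$w[idx] else rep(1, length(idx))
  X <- if (include_genotype) cbind(cohort$Z, cohort$G)[idx, , drop = FALSE]
       else cohort$Z[idx, , drop = FALSE]
  wgee_fit(X, st$y[idx], w, ...)
}
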