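#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats sd var cov qnorm pnorm dnorm lm coef anova predict
#'   rnorm runif median complete.cases quantile confint pf pt setNames
#' @importFrom utils head
## usethis namespace: end
NULL

# Columns of a feature table that hold features (everything except the
# subject identifier and the group label).
feature_cols <- function(data) {
  setdiff(names(data), c("subject_id", "group"))
}

feature_matrix <- function(data) {
  fc <- feature_cols(data)
  m <- as.matrix(data[fc])
  if (!is.numeric(m)) {
    abort("feature columns must be numeric")
  }
  rownames(m) <- data$subject_id
  m
}

# Validate the subject_id/group contract shared by every pipeline stage.
# Returns the group factor (control level first).
check_groups <- function(data, min_per_group = 3L) {
  if (!all(c("subject_id", "group") %in% names(data))) {
    abort("feature table needs `subject_id` and `group` columns")
  }
  if (anyDuplicated(data$subject_id)) {
    abort("duplicate subject ids")
  }
  g <- as_group_factor(data$group)
  if (nlevels(g) != 2L) {
    abort("two groups required")
  }
  if (any(table(g) < min_per_group)) {
    abort(sprintf("each group needs at least %d subjects", min_per_group))
  }
  g
}

# Standardize the group column: factor with the control level first.
# "WT" is recognized as control when present; otherwise the first level of
# factor(), i.e. alphabetical order, is taken as control.
as_group_factor <- function(group) {
  g <- factor(group)
  if ("WT" %in% levels(g)) {
    g <- stats::relevel(g, ref = "WT")
  }
  g
}

# Run `expr` under a temporary RNG state seeded with `seed` (global state
# untouched). All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Log-density of a multivariate normal at the rows of x, via the Cholesky
# factor of sigma. Small helper; sampling goes through MASS::mvrnorm.
dmvnorm_log <- function(x, mean, sigma) {
  x <- matrix(x, ncol = length(mean))
  k <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * k * log(2 * pi)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
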