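#' Construct a grouped zero-inflated count regression dataset
#'
#' Bundles a nonnegative integer response with the count-component and
#' zero-component design matrices and a group partition of the penalized
#' columns. Factor columns are dummy-coded (reference level dropped) and every
#' dummy inherits the factor's group label. The two intercepts and the
#' dispersion are never penalized; they form "group 0".
#'
#' @param data A data frame containing the response and all predictors.
#' @param response Name of the response column (nonnegative integers).
#' @param groups Named character or numeric vector mapping predictor column
#'   names to group labels for the count component, or a two-column data frame
#'   with columns `term` and `group`. Every predictor used must appear.
#' @param zero_groups Grouping for the zero-inflation component; defaults to
#'   `groups` (same covariates in both components).
#' @return An object of class `zinb_data`: a list with elements `y`, `X`, `Z`
#'   (designs including a leading intercept column), `beta_groups`,
#'   `gamma_groups` (integer labels per penalized column) and bookkeeping.
#' @export
#' @examples
#' df <- data.frame(visits = rpois(20, 2), age = rnorm(20), sex = gl(2, 10))
#' d <- zinb_data(df, "visits", c(age = 1, sex = 2))
#' d$beta_groups
zinb_data <- function(data, response, groups, zero_groups = groups) {
  stopifnot(is.data.frame(data), is.character(response), length(response) == 1)
  if (!response %in% names(data)) {
    stop("missing_response_column: response column '", response,
         "' not found in data", call. = FALSE)
  }
  y <- data[[response]]
  gmap <- normalize_group_map(groups)
  zmap <- normalize_group_map(zero_groups)
  miss <- setdiff(c(names(gmap), names(zmap)), names(data))
  if (length(miss) > 0) {
    stop("missing_predictor_column: column(s) ", paste(miss, collapse = ", "),
         " not found in data", call. = FALSE)
  }
  Xb <- expand_design(data, names(gmap), gmap)
  Zb <- expand_design(data, names(zmap), zmap)
  new_zinb_data(y, cbind(`(Intercept)` = 1, Xb$mat),
                cbind(`(Intercept)` = 1, Zb$mat),
                Xb$groups, Zb$groups)
}

#' Low-level constructor from matrices
#'
#' @param y Nonnegative integer response vector.
#' @param X Count-component design, `n x (1+p)`, leading all-ones column.
#' @param Z Zero-component design, `n x (1+q)`, leading all-ones column.
#' @param beta_groups Integer group labels (1..K) for the `p` penalized
#'   X-columns, in column order.
#' @param gamma_groups Likewise for the `q` penalized Z-columns.
#' @return A `zinb_data` object.
#' @export
new_zinb_data <- function(y, X, Z, beta_groups, gamma_groups) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1) stop("empty_response: n must be >= 1", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    stop("invalid_response: response must be nonnegative integers",
         call. = FALSE)
  }
  if (nrow(X) != n || nrow(Z) != n) {
    stop("dimension_mismatch: designs must have length(y) rows", call. = FALSE)
  }
  if (any(X[, 1] != 1) || any(Z[, 1] != 1)) {
    stop("invalid_design: leading column of X and Z must be all ones",
         call. = FALSE)
  }
  p <- ncol(X) - 1L; q <- ncol(Z) - 1L
  beta_groups <- as.integer(beta_groups)
  gamma_groups <- as.integer(gamma_groups)
  if (length(beta_groups) != p || length(gamma_groups) != q) {
    stop("unmapped_column: every penalized column needs exactly one group label",
         call. = FALSE)
  }
  if ((p > 0 && any(beta_groups < 1)) || (q > 0 && any(gamma_groups < 1))) {
    stop("invalid_group_label: penalized group labels must be >= 1 (0 is the ",
         "unpenalized intercept/dispersion block)", call. = FALSE)
  }
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", if (p > 0) paste0("x", seq_len(p)))
  }
  if (is.null(colnames(Z))) {
    colnames(Z) <- c("(Intercept)", if (q > 0) paste0("z", seq_len(q)))
  }
  structure(list(y = y, X = X, Z = Z,
                 beta_groups = beta_groups, gamma_groups = gamma_groups,
                 n = n, p = p, q = q),
            class = "zinb_data")
}

normalize_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("term", "group") %in% names(groups)))
    out <- groups$group
    names(out) <- groups$term
    return(out)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("invalid_group_map: groups must be a named vector or a term/group ",
         "data frame", call. = FALSE)
  }
  groups
}

# Dummy-code factors/characters, keep numerics as-is; group labels relabelled
# to consecutive integers in first-appearance order.
expand_design <- function(data, cols, gmap) {
  pieces <- list(); glab <- character(0)
  for (cn in cols) {
    v <- data[[cn]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cn, levels(v)[-1])
      pieces[[cn]] <- mm
      glab <- c(glab, rep(as.character(gmap[[cn]]), ncol(mm)))
    } else {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cn))
      pieces[[cn]] <- m
      glab <- c(glab, as.character(gmap[[cn]]))
    }
  }
  mat <- do.call(cbind, pieces)
  labs <- unique(glab)
  list(mat = mat, groups = match(glab, labs))
}

#' @export
print.zinb_data <- function(x, ...) {
  cat("<zinb_data> n =", x$n, "\n")
  cat("  count component: ", x$p, " penalized columns in ",
      length(unique(x$beta_groups)), " groups\n", sep = "")
  cat("  zero component:  ", x$q, " penalized columns in ",
      length(unique(x$gamma_groups)), " groups\n", sep = "")
  cat("  zeros in y: ", sum(x$y == 0), "/", x$n, "\n", sep = "")
  invisible(x)
}

# ---- parameter vector plumbing -------------------------------------------
# Full parameter ordering, fixed package-wide:
#   theta = (log_phi, beta0, beta[1..p], gamma0, gamma[1..q])
# The penalized stacked vector is (beta, gamma); group 0 is
# {log_phi, beta0, gamma0}.

theta_dim <- function(data) 3L + data$p + data$q

theta_index <- function(data) {
  p <- data$p; q <- data$q
  list(log_phi = 1L, beta0 = 2L,
       beta = if (p > 0) 2L + seq_len(p) else integer(0),
       gamma0 = 3L + p,
       gamma = if (q > 0) 3L + p + seq_len(q) else integer(0),
       group0 = c(1L, 2L, 3L + p))
}

#' Bundle ZINB parameters
#'
#' @param beta0,gamma0 Intercepts of the count (log link) and zero (logit
#'   link) components.
#' @param beta,gamma Penalized coefficient vectors.
#' @param log_phi Natural log of the NB dispersion (phi = exp(log_phi) > 0).
#' @return A `zinb_params` object.
#' @export
zinb_params <- function(beta0 = 0, beta = numeric(0), gamma0 = 0,
                        gamma = numeric(0), log_phi = 0) {
  structure(list(beta0 = as.numeric(beta0), beta = as.numeric(beta),
                 gamma0 = as.numeric(gamma0), gamma = as.numeric(gamma),
                 log_phi = as.numeric(log_phi)),
            class = "zinb_params")
}

theta_pack <- function(params) {
  c(params$log_phi, params$beta0, params$beta, params$gamma0, params$gamma)
}

theta_unpack <- function(theta, data) {
  ix <- theta_index(data)
  zinb_params(beta0 = theta[ix$beta0], beta = theta[ix$beta],
              gamma0 = theta[ix$gamma0], gamma = theta[ix$gamma],
              log_phi = theta[ix$log_phi])
}

as_theta <- function(x, data) {
  if (inherits(x, "zinb_params")) theta_pack(x) else as.numeric(x)
}

# Penalized group layout over theta coordinates. Returns a list with one
# element per penalized group: id ("count:3" / "zero:1"), component, label,
# theta indices, size.
group_layout <- function(data) {
  ix <- theta_index(data)
  out <- list()
  for (k in sort(unique(data$beta_groups))) {
    out[[length(out) + 1L]] <- list(id = paste0("count:", k),
                                    component = "count", label = k,
                                    idx = ix$beta[data$beta_groups == k])
  }
  for (k in sort(unique(data$gamma_groups))) {
    out[[length(out) + 1L]] <- list(id = paste0("zero:", k),
                                    component = "zero", label = k,
                                    idx = ix$gamma[data$gamma_groups == k])
  }
  for (i in seq_along(out)) out[[i]]$size <- length(out[[i]]$idx)
  out
}
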