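#' Specify a PLS path model
#'
#' A PLS-PM specification is a reflective measurement model (named blocks of
#' indicator columns, each indicator in exactly one block) plus a structural
#' model (a directed acyclic graph of paths between constructs).
#'
#' @param blocks Named list: construct name -> character vector of indicator
#'   column names.
#' @param paths Two-column data frame or matrix of construct names
#'   (`from`, `to`).
#' @return A validated `hemsim_plspm_spec` list.
#' @export
plspm_spec <- function(blocks, paths) {
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  names(paths) <- c("from", "to")
  constructs <- names(blocks)
  if (is.null(constructs) || any(constructs == "")) {
    stop("`blocks` must be a named list", call. = FALSE)
  }
  ind <- unlist(blocks)
  if (anyDuplicated(ind)) {
    stop("every indicator must belong to exactly one block", call. = FALSE)
  }
  bad <- !(paths$from %in% constructs & paths$to %in% constructs)
  if (any(bad)) stop("paths refer to unknown constructs", call. = FALSE)
  if (has_cycle(constructs, paths)) {
    stop("the structural model must be acyclic", call. = FALSE)
  }
  structure(list(blocks = blocks, paths = paths), class = "hemsim_plspm_spec")
}

has_cycle <- function(constructs, paths) {
  adj <- split(paths$to, factor(paths$from, levels = constructs))
  state <- stats::setNames(rep(0L, length(constructs)), constructs)
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(constructs, visit, logical(1)))
}

#' Fit a PLS path model
#'
#' Lohmoeller-style partial least squares path modeling with the path
#' weighting scheme and reflective (mode A) outer estimation: indicators are
#' standardized, outer weights are iterated to convergence of the composite
#' scores, inner path coefficients are estimated by per-endogenous-construct
#' least squares on the scores, and construct reliability (Cronbach's alpha,
#' Dijkstra-Henseler rho_a, composite reliability rho_c) and convergent
#' validity (AVE) are reported per block. Indirect effects are products of
#' the direct path coefficients along each chain.
#'
#' @param data Data frame containing all indicator columns (no missing
#'   values; n >= 10 rows).
#' @param spec A [plspm_spec()].
#' @param max_iter Outer iteration cap.
#' @param tol Convergence tolerance on the outer weights.
#' @return An object of class `hemsim_plspm` with `paths` (standardized
#'   coefficients), `outer` (weights and loadings), `reliability` (alpha,
#'   rho_a, rho_c, AVE per construct), `indirect` (all chain products),
#'   `scores`, `r_squared`, `iterations` and `converged`. Supports
#'   [tidy()] and [glance()].
#' @export
fit_plspm <- function(data, spec, max_iter = 300, tol = 1e-7) {
  stopifnot(inherits(spec, "hemsim_plspm_spec"))
  blocks <- spec$blocks
  paths <- spec$paths
  constructs <- names(blocks)
  ind_cols <- unlist(blocks)
  if (nrow(data) < 10) stop("PLS-PM needs at least 10 rows", call. = FALSE)
  X <- as.matrix(data[, ind_cols, drop = FALSE])
  if (anyNA(X)) stop("indicator data contain missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("indicator(s) with zero variance: ",
         paste(ind_cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  X <- scale(X)
  n <- nrow(X)
  k <- length(constructs)
  block_of <- rep(constructs, lengths(blocks))

  std <- function(v) v / stats::sd(v)
  score <- function(w) {
    Y <- matrix(0, n, k, dimnames = list(NULL, constructs))
    for (j in seq_len(k)) {
      xb <- X[, block_of == constructs[j], drop = FALSE]
      Y[, j] <- std(xb %*% w[block_of == constructs[j]])
    }
    Y
  }

  w <- rep(1, length(ind_cols))
  Y <- score(w)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # inner estimation: path weighting scheme
    Z <- matrix(0, n, k, dimnames = list(NULL, constructs))
    for (j in seq_len(k)) {
      cj <- constructs[j]
      pred <- paths$from[paths$to == cj]
      succ <- paths$to[paths$from == cj]
      zj <- rep(0, n)
      if (length(pred)) {
        b <- stats::coef(stats::lm.fit(cbind(1, Y[, pred, drop = FALSE]),
                                       Y[, cj]))[-1]
        zj <- zj + Y[, pred, drop = FALSE] %*% b
      }
      if (length(succ)) {
        r <- drop(stats::cor(Y[, cj], Y[, succ, drop = FALSE]))
        zj <- zj + Y[, succ, drop = FALSE] %*% r
      }
      if (all(zj == 0)) zj <- Y[, cj] # isolated construct
      Z[, j] <- std(zj)
    }
    # outer estimation: mode A weights, oriented with the block consensus
    w_new <- vapply(seq_along(ind_cols), function(i) {
      stats::cor(X[, i], Z[, match(block_of[i], constructs)])
    }, numeric(1))
    for (j in seq_len(k)) {
      sel <- block_of == constructs[j]
      if (sum(w_new[sel]) < 0) w_new[sel] <- -w_new[sel]
    }
    delta <- max(abs(abs(w_new) - abs(w)))
    w <- w_new
    Y <- score(w)
    if (delta < tol) { converged <- TRUE; break }
  }

  loadings <- vapply(seq_along(ind_cols), function(i) {
    stats::cor(X[, i], Y[, match(block_of[i], constructs)])
  }, numeric(1))

  # inner model: OLS per endogenous construct on standardized scores
  endo <- unique(paths$to)
  path_rows <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (cj in endo) {
    pred <- paths$from[paths$to == cj]
    fitj <- stats::lm.fit(cbind(1, Y[, pred, drop = FALSE]), Y[, cj])
    b <- stats::coef(fitj)[-1]
    r2[cj] <- 1 - sum(fitj$residuals^2) / sum((Y[, cj] - mean(Y[, cj]))^2)
    path_rows[[cj]] <- tibble::tibble(from = pred, to = cj,
                                      estimate = unname(b))
  }
  path_tbl <- dplyr::bind_rows(path_rows)

  reliability <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
    sel <- block_of == constructs[j]
    block_reliability(X[, sel, drop = FALSE], w[sel], loadings[sel],
                      constructs[j])
  }))

  out <- list(
    spec = spec,
    paths = path_tbl,
    outer = tibble::tibble(construct = block_of, indicator = ind_cols,
                           weight = w, loading = loadings),
    reliability = reliability,
    scores = tibble::as_tibble(as.data.frame(Y)),
    r_squared = r2,
    iterations = it,
    converged = converged,
    n = n
  )
  out$indirect <- indirect_effects(out)
  class(out) <- "hemsim_plspm"
  out
}

block_reliability <- function(Xb, w, lambda, name) {
  p <- ncol(Xb)
  if (p == 1) {
    return(tibble::tibble(construct = name, n_indicators = 1L, alpha = 1,
                          rho_a = 1, rho_c = 1, ave = 1))
  }
  S <- stats::cor(Xb)
  rbar <- mean(S[lower.tri(S)])
  alpha <- p * rbar / (1 + (p - 1) * rbar)
  lam <- abs(lambda)
  rho_c <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  ave <- mean(lam^2)
  # Dijkstra-Henseler rho_a, with weights on the unit-composite-variance
  # scale (w' S w = 1), the convention the estimator assumes
  wn <- w / sqrt(drop(t(w) %*% S %*% w))
  num <- drop(t(wn) %*% (S - diag(diag(S))) %*% wn)
  den <- drop(t(wn) %*% (wn %*% t(wn) - diag(diag(wn %*% t(wn)))) %*% wn)
  rho_a <- drop(sum(wn^2))^2 * num / den
  tibble::tibble(construct = name, n_indicators = p, alpha = alpha,
                 rho_a = rho_a, rho_c = rho_c, ave = ave)
}

#' Specific indirect effects
#'
#' Enumerates every directed chain of length two or more through the
#' structural model and multiplies the direct path coefficients along it.
#'
#' @param fit A `hemsim_plspm` object.
#' @param chains Optional list of character vectors (construct sequences);
#'   by default all chains in the DAG are enumerated. Chains not present in
#'   the model are an error.
#' @return Tibble with `chain` (" -> "-separated) and `estimate`.
#' @export
indirect_effects <- function(fit, chains = NULL) {
  paths <- fit$paths
  edge <- function(a, b) {
    e <- paths$estimate[paths$from == a & paths$to == b]
    if (!length(e)) stop("chain uses a path absent from the model: ",
                         a, " -> ", b, call. = FALSE)
    e
  }
  if (is.null(chains)) {
    chains <- list()
    grow <- function(chain) {
      nxt <- paths$to[paths$from == chain[length(chain)]]
      for (v in nxt) {
        ch <- c(chain, v)
        if (length(ch) >= 3) chains[[length(chains) + 1]] <<- ch
        grow(ch)
      }
    }
    for (v in unique(paths$from)) grow(v)
  }
  if (!length(chains)) {
    return(tibble::tibble(chain = character(), estimate = numeric()))
  }
  tibble::tibble(
    chain = vapply(chains, paste, character(1), collapse = " -> "),
    estimate = vapply(chains, function(ch) {
      prod(vapply(seq_len(length(ch) - 1),
                  function(i) edge(ch[i], ch[i + 1]), numeric(1)))
    }, numeric(1))
  )
}

#' @rdname fit_plspm
#' @param x A `hemsim_plspm` object.
#' @param ... Unused.
#' @export
tidy.hemsim_plspm <- function(x, ...) x$paths

#' @rdname fit_plspm
#' @export
glance.hemsim_plspm <- function(x, ...) {
  tibble::tibble(n = x$n, iterations = x$iterations,
                 converged = x$converged,
                 mean_r_squared = mean(x$r_squared))
}

#' @export
print.hemsim_plspm <- function(x, ...) {
  cat("<hemsim_plspm> ", x$n, "rows,", x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$paths)
  print(x$reliability)
  invisible(x)
}

#' PLS-PM indicator table and specification for a sweep
#'
#' `sweep_plspm_data()` assembles the per-scenario indicator table from a
#' sweep result (configuration variables plus monthly canopy aggregates and
#' the final bud dry mass); `sweep_plspm_spec()` gives the matching
#' measurement blocks and the structural graph: the four configuration
#' constructs feed leaf radiation and leaf temperature, radiation feeds
#' temperature and photosynthesis, temperature feeds photosynthesis, and
#' photosynthesis feeds the bud.
#'
#' @param sweep A `hemsim_sweep` tibble from [run_sweep()].
#' @return A tibble (data) or a `hemsim_plspm_spec` (spec).
#' @export
sweep_plspm_data <- function(sweep) {
  months <- function(prefix) paste0(prefix, "_m", 4:8)
  cols <- c(months("rad"), months("tleaf"), months("anet"))
  missing <- setdiff(cols, names(sweep))
  if (length(missing)) {
    stop("sweep lacks indicator columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(
      id = sweep$id,
      pattern_code = match(sweep$pattern, c("DRBR", "ER", "NWR")),
      wide_row = sweep$wide_row,
      wn_sum = sweep$wn_sum,
      plant_spacing = sweep$plant_spacing,
      density = sweep$density_realized,
      bud_dm = sweep$bud_dm_g
    ),
    sweep[, cols]
  )
}

#' @rdname sweep_plspm_data
#' @export
sweep_plspm_spec <- function() {
  months <- function(prefix) paste0(prefix, "_m", 4:8)
  blocks <- list(
    pattern = "pattern_code",
    row_distance = c("wide_row", "wn_sum"),
    plant_spacing = "plant_spacing",
    density = "density",
    leaf_radiation = months("rad"),
    leaf_temperature = months("tleaf"),
    leaf_photosynthesis = months("anet"),
    bud = "bud_dm"
  )
  config <- c("pattern", "row_distance", "plant_spacing", "density")
  paths <- rbind(
    data.frame(from = config, to = "leaf_radiation"),
    data.frame(from = config, to = "leaf_temperature"),
    data.frame(from = "leaf_radiation", to = "leaf_temperature"),
    data.frame(from = "leaf_radiation", to = "leaf_photosynthesis"),
    data.frame(from = "leaf_temperature", to = "leaf_photosynthesis"),
    data.frame(from = "leaf_photosynthesis", to = "bud")
  )
  plspm_spec(blocks, paths)
}
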