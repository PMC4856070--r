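# Posterior prediction, cross-validation and the predictive checks
# (Spearman correlation, MSEP, posterior-mean log-likelihood).

#' Posterior predicted counts
#'
#' For each target record the prediction averages, over the retained draws,
#' `exp(x' beta*(s) + log r(s) + g_j(s) + gE_ij(s))` -- i.e. the posterior
#' mean of `mu` on the count scale.  Records may reference lines or cells
#' without training observations; their genetic and GxE draws come from the
#' conditional prior as sampled, which is exactly how unphenotyped lines are
#' predicted in GBLUP.
#'
#' @param fit a `bmnb_fit`.
#' @param newdata data.frame with columns `env`, `line`, and `block` when the
#'   fit includes block effects.  Labels must belong to the fitted level sets.
#' @return numeric vector of strictly positive predicted counts.
#' @export
predict_counts <- function(fit, newdata) {
  stopifnot(inherits(fit, "bmnb_fit"))
  m <- fit$meta
  if (!all(c("env", "line") %in% names(newdata)))
    stop("'newdata' needs columns env and line")
  ei <- match(as.character(newdata$env), m$env_levels)
  if (anyNA(ei))
    stop("unknown environment label: ", newdata$env[which(is.na(ei))[1]])
  li <- match(as.character(newdata$line), m$line_levels)
  if (anyNA(li))
    stop("unknown line label: ", newdata$line[which(is.na(li))[1]])
  blk_col <- rep(NA_integer_, nrow(newdata))
  if (m$include_blocks) {
    if (!"block" %in% names(newdata))
      stop("fit includes block effects; 'newdata' needs a block column")
    want <- paste0("env", newdata$env, ".blk", newdata$block)
    blk_col <- match(want, m$x_colnames)  # NA = dropped/absent column -> 0
    bi <- match(as.character(newdata$block), m$block_levels)
    if (anyNA(bi))
      stop("unknown block label: ", newdata$block[which(is.na(bi))[1]])
  }
  ch <- fit$chains
  J <- m$J
  vapply(seq_len(nrow(newdata)), function(k) {
    eta_star <- ch$beta_star[, ei[k]] + ch$b1[, li[k]] +
      (if (m$interaction) ch$b2[, (ei[k] - 1L) * J + li[k]] else 0)
    if (m$include_blocks && !is.na(blk_col[k]))
      eta_star <- eta_star + ch$beta_star[, blk_col[k]]
    mean(ch$r * exp(eta_star))
  }, numeric(1))
}

#' @export
predict.bmnb_fit <- function(object, newdata, ...) {
  predict_counts(object, newdata)
}

#' Spearman rank correlation between observed and predicted values
#'
#' Average ranks are used for ties (counts produce many).  When either vector
#' is constant the correlation is undefined and `NA` is returned with a
#' warning.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_cor <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2 ||
      length(unique(observed)) < 2 || length(unique(predicted)) < 2) {
    warning("Spearman correlation undefined for constant input; returning NA")
    return(NA_real_)
  }
  cor(observed, predicted, method = "spearman")
}

#' Mean squared error of prediction
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return non-negative scalar, `mean((observed - predicted)^2)`.
#' @export
msep <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  mean((observed - predicted)^2)
}

# subset a panel's records while preserving the full level sets and dims
panel_subset <- function(panel, rows) {
  out <- as.data.frame(panel)[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            I = attr(panel, "I"), J = attr(panel, "J"), K = attr(panel, "K"),
            n_T = nrow(out),
            env_levels = attr(panel, "env_levels"),
            line_levels = attr(panel, "line_levels"),
            block_levels = attr(panel, "block_levels"),
            class = c("bmnb_panel", "data.frame"))
}

# random k-fold partition of records; each fold's training set must retain
# every environment
make_folds <- function(panel, k, stratify_env = FALSE, max_retries = 100) {
  n <- attr(panel, "n_T")
  if (k < 2 || k > n) stop("'k' must be between 2 and the number of records")
  for (try_i in seq_len(max_retries)) {
    if (stratify_env) {
      fold <- integer(n)
      for (i in unique(panel$env_idx)) {
        rows <- which(panel$env_idx == i)
        fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(panel$env_idx[fold != f])) == attr(panel, "I"),
      logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds whose training sets retain every environment; ",
       "try stratify_env = TRUE or fewer folds")
}

#' k-fold cross-validation of predictive accuracy
#'
#' Randomly partitions the records into `k` mutually exclusive folds (sizes
#' differing by at most one); for each fold the model is fitted on the other
#' `k - 1` folds and the held-out records are predicted.  Spearman
#' correlation and MSEP are computed per environment on the validation
#' records only, then summarized (mean and SD) across folds.
#'
#' @param panel a [count_panel()].
#' @param markers optional marker matrix (GRM-based line covariance); `NULL`
#'   uses an identity (i.i.d. line effects).
#' @param k number of folds (default 10).
#' @param model,include_blocks,interaction,prior,iterations,burn_in,fixed_r
#'   passed to [bmnb_fit()].
#' @param stratify_env build folds within environment.
#' @param seed optional integer seed governing fold assignment and all fits.
#' @return object of class `bmnb_cv`: `folds` (assignment vector),
#'   `per_fold` (fold x environment metrics), `by_env` (per-environment mean
#'   and SD across folds), `overall` (pooled across environments).
#' @export
cross_validate <- function(panel, markers = NULL, k = 10,
                           model = c("nb", "pois"),
                           include_blocks = TRUE, interaction = TRUE,
                           prior = NULL,
                           iterations = 60000L, burn_in = 30000L,
                           fixed_r = NULL, stratify_env = FALSE,
                           seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(panel, "bmnb_panel"))
  if (!is.null(seed)) set.seed(seed)
  fold <- make_folds(panel, k, stratify_env = stratify_env)

  env_levels <- attr(panel, "env_levels")
  rows <- list()
  for (f in seq_len(k)) {
    train <- panel_subset(panel, which(fold != f))
    valid <- as.data.frame(panel)[fold == f, , drop = FALSE]
    fit <- bmnb_fit(train, markers = markers, model = model,
                    include_blocks = include_blocks,
                    interaction = interaction, prior = prior,
                    iterations = iterations, burn_in = burn_in,
                    fixed_r = fixed_r)
    pred <- predict_counts(fit, valid)
    for (e in env_levels) {
      sel <- valid$env == e
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, env = e, n = sum(sel),
        cor = suppressWarnings(spearman_cor(valid$count[sel], pred[sel])),
        msep = msep(valid$count[sel], pred[sel]))
    }
  }
  per_fold <- do.call(rbind, rows)
  by_env <- do.call(rbind, lapply(split(per_fold, per_fold$env), function(d)
    data.frame(env = d$env[1],
               cor_mean = mean(d$cor, na.rm = TRUE),
               cor_sd = sd(d$cor, na.rm = TRUE),
               msep_mean = mean(d$msep), msep_sd = sd(d$msep))))
  rownames(by_env) <- NULL
  overall <- data.frame(cor_mean = mean(per_fold$cor, na.rm = TRUE),
                        msep_mean = mean(per_fold$msep))
  structure(list(folds = fold, per_fold = per_fold, by_env = by_env,
                 overall = overall, k = k),
            class = "bmnb_cv")
}

#' @export
print.bmnb_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  print(x$by_env, digits = 3, ...)
  invisible(x)
}

#' Posterior-mean log-likelihood
#'
#' Average over the retained draws of the total NB log-likelihood
#' `sum nb_log_pmf(y; eta*, r)`; the goodness-of-fit summary used to compare
#' linear-predictor scenarios.  With `panel = NULL` the value stored per draw
#' at fit time is averaged; supplying a panel recomputes the quantity for
#' those records (the panel must share the fit's level sets).
#'
#' @param fit a `bmnb_fit`.
#' @param panel optional [count_panel()].
#' @return scalar.
#' @export
posterior_loglik <- function(fit, panel = NULL) {
  if (is.null(panel)) return(mean(fit$chains$loglik))
  stopifnot(inherits(panel, "bmnb_panel"))
  m <- fit$meta; ch <- fit$chains
  ei <- match(panel$env, m$env_levels)
  li <- match(panel$line, m$line_levels)
  if (anyNA(ei) || anyNA(li)) stop("panel labels unknown to the fit")
  cell <- (ei - 1L) * m$J + li
  blk_col <- rep(NA_integer_, nrow(panel))
  if (m$include_blocks)
    blk_col <- match(paste0("env", panel$env, ".blk", panel$block), m$x_colnames)
  M <- m$n_kept
  ll <- numeric(M)
  for (s in seq_len(M)) {
    eta <- ch$beta_star[s, ei] + ch$b1[s, li] +
      (if (m$interaction) ch$b2[s, cell] else 0)
    add <- !is.na(blk_col)
    if (any(add)) eta[add] <- eta[add] + ch$beta_star[s, blk_col[add]]
    ll[s] <- sum(nb_log_pmf(panel$count, eta, ch$r[s]))
  }
  mean(ll)
}

#' Compare linear-predictor scenarios by cross-validation
#'
#' Fits and cross-validates the four standard scenario variants:
#' S1 = environment + i.i.d. lines + blocks; S2 = environment +
#' marker-informed lines (GRM) + blocks; S3 = S1 plus the GxE interaction;
#' S4 = S2 plus the GxE interaction.  Reports Spearman correlation and MSEP
#' per environment (mean and SD across folds), the full-data posterior-mean
#' log-likelihood per scenario, and per-environment rank averages across
#' scenarios (ranks averaged over the two predictive checks, ties getting
#' average ranks; lower is better).
#'
#' @param panel a [count_panel()].
#' @param markers marker matrix; required for S2/S4.
#' @param scenarios subset of `c("S1", "S2", "S3", "S4")`.
#' @param k,model,iterations,burn_in,seed passed to [cross_validate()] /
#'   [bmnb_fit()].
#' @return object of class `bmnb_scenario_table`: `checks` (scenario x env
#'   metric table), `loglik` (per scenario), `rank_avg` (scenario x env).
#' @export
scenario_table <- function(panel, markers = NULL,
                           scenarios = c("S1", "S2", "S3", "S4"),
                           k = 10, model = c("nb", "pois"),
                           iterations = 60000L, burn_in = 30000L,
                           seed = NULL) {
  model <- match.arg(model)
  scenarios <- match.arg(scenarios, c("S1", "S2", "S3", "S4"),
                         several.ok = TRUE)
  spec <- list(S1 = list(markers = FALSE, interaction = FALSE),
               S2 = list(markers = TRUE, interaction = FALSE),
               S3 = list(markers = FALSE, interaction = TRUE),
               S4 = list(markers = TRUE, interaction = TRUE))
  if (is.null(markers) && any(vapply(spec[scenarios], `[[`, logical(1), "markers")))
    stop("scenarios S2/S4 require a marker matrix")
  if (!is.null(seed)) set.seed(seed)

  checks <- list(); loglik <- setNames(numeric(0), character(0))
  for (sc in scenarios) {
    mk <- if (spec[[sc]]$markers) markers else NULL
    cv <- cross_validate(panel, markers = mk, k = k, model = model,
                         include_blocks = TRUE,
                         interaction = spec[[sc]]$interaction,
                         iterations = iterations, burn_in = burn_in)
    fit <- bmnb_fit(panel, markers = mk, model = model,
                    include_blocks = TRUE,
                    interaction = spec[[sc]]$interaction,
                    iterations = iterations, burn_in = burn_in)
    loglik[sc] <- posterior_loglik(fit)
    d <- cv$by_env; d$scenario <- sc
    checks[[sc]] <- d
  }
  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL

  # per-environment rank averages over the two checks
  rank_rows <- lapply(split(checks, checks$env), function(d) {
    rc <- rank(-d$cor_mean)        # higher correlation is better
    rm_ <- rank(d$msep_mean)       # lower error is better
    data.frame(scenario = d$scenario, env = d$env[1],
               rank_avg = (rc + rm_) / 2)
  })
  rank_avg <- do.call(rbind, rank_rows)
  rownames(rank_avg) <- NULL
  structure(list(checks = checks, loglik = loglik, rank_avg = rank_avg),
            class = "bmnb_scenario_table")
}

#' @export
print.bmnb_scenario_table <- function(x, ...) {
  cat("cross-validated predictive checks by scenario\n")
  print(x$checks, digits = 3, ...)
  cat("\nposterior-mean log-likelihood\n")
  print(round(x$loglik, 2))
  cat("\nrank averages (lower is better)\n")
  print(x$rank_avg, digits = 3, ...)
  invisible(x)
}
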