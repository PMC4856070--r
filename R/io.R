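# CSV plumbing for phenotype panels, marker matrices and chains, plus the
# rule for fixing the dispersion in the Poisson special case.

#' Dispersion value for the Poisson special case
#'
#' The NB model converges to the Poisson as `r` grows; fitting Poisson data
#' with a large fixed `r` is accurate as long as `r` dominates the mean count.
#' The rule: mean count below 50 uses `r = 1000`; between 50 and 200 uses
#' `r = 5000`; above 200 uses `r = 10000`.  Boundary values are assigned the
#' larger `r` (the conservative side).
#'
#' @param mean_count estimate of the mean count of the data.
#' @return 1000, 5000 or 10000.
#' @export
auto_fix_r <- function(mean_count) {
  stopifnot(is.finite(mean_count), mean_count >= 0)
  if (mean_count < 50) 1000
  else if (mean_count < 200) 5000
  else 10000
}

#' Read a phenotype panel from CSV
#'
#' Expects a header with columns `env`, `block`, `line`, `rep`, `count`;
#' validation (non-negative integer counts, no duplicate records) is done by
#' [count_panel()], which names the offending row in its errors.
#'
#' @param path CSV file path.
#' @return a [count_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty phenotype file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  count_panel(df)
}

#' Write a phenotype panel to CSV
#'
#' @param panel a [count_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "bmnb_panel"))
  write.csv(as.data.frame(panel)[, c("env", "block", "line", "rep", "count")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker matrix from CSV
#'
#' First column: line label; remaining columns: 0/1 marker codes (`NA`
#' allowed; filter and impute with [maf_filter()]).
#'
#' @param path CSV file path.
#' @return numeric matrix, lines as rows with rownames.
#' @export
load_markers <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty marker file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("marker file needs a line column plus markers: ", path)
  W <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(W) <- "double"
  bad <- which(!(W %in% c(0, 1) | is.na(W)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary marker code at line %s, marker %s",
                 df[[1]][bad[1, 1]], colnames(W)[bad[1, 2]]))
  rownames(W) <- as.character(df[[1]])
  W
}

#' Export retained chains and a reproducibility manifest
#'
#' Writes `<prefix>_scalars.csv` (one row per retained draw: back-transformed
#' fixed effects, `r`, variance components, log-likelihood),
#' `<prefix>_b1.csv`, `<prefix>_b2.csv`, and `<prefix>_manifest.json`
#' containing the run configuration (seed, iterations, priors, package
#' version) sufficient to reproduce the run bit-identically.
#'
#' @param fit a `bmnb_fit`.
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_chains <- function(fit, prefix) {
  stopifnot(inherits(fit, "bmnb_fit"))
  ch <- fit$chains
  scalars <- data.frame(ch$beta, check.names = FALSE)
  names(scalars) <- paste0("beta.", colnames(ch$beta))
  scalars$r <- ch$r
  scalars$sigma_b1_sq <- ch$sigma_b1_sq
  scalars$sigma_b2_sq <- ch$sigma_b2_sq
  scalars$loglik <- ch$loglik
  files <- paste0(prefix, c("_scalars.csv", "_b1.csv", "_b2.csv",
                            "_manifest.json"))
  write.csv(scalars, files[1], row.names = FALSE)
  write.csv(as.data.frame(ch$b1), files[2], row.names = FALSE)
  write.csv(as.data.frame(ch$b2), files[3], row.names = FALSE)
  m <- fit$meta
  manifest <- list(
    package = "bmnb", version = as.character(packageVersion("bmnb")),
    iterations = m$iterations, burn_in = m$burn_in, thin = m$thin,
    seed = m$seed, fixed_r = m$fixed_r, interaction = m$interaction,
    dims = list(I = m$I, J = m$J, K = m$K, p = m$p, n_T = m$n_T),
    prior = m$prior[c("beta0", "nu_b1", "S_b1", "nu_b2", "S_b2",
                      "a0", "b0", "flat_beta")])
  jsonlite::write_json(manifest, files[4], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(files)
}
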