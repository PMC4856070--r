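#' Construct a count panel
#'
#' Validates and canonically orders a long-format table of count observations
#' from a multi-environment trial: one row per replicate `t` of line `j` in
#' block `k` of environment `i`.  Records are reordered environment-major,
#' then line, then block, then replicate, which fixes the stacking convention
#' shared by the design matrices and the latent-variable vectors.
#'
#' @param data data.frame with columns `env`, `block`, `line`, `rep`, `count`.
#' @return object of class `bmnb_panel`: the ordered data plus integer index
#'   columns `env_idx`, `line_idx`, `block_idx`, `cell_idx`
#'   (`cell = (env - 1) * J + line`, environment-major) and attributes
#'   `I`, `J`, `K`, `n_T` and the level sets.
#' @export
count_panel <- function(data) {
  need <- c("env", "block", "line", "rep", "count")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("panel has no records")
  y <- data$count
  if (any(!is.finite(y)))
    stop("non-finite count at row ", which(!is.finite(y))[1])
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers; offending row ",
         which(y < 0 | y != round(y))[1])
  key <- paste(data$env, data$line, data$block, data$rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (env, line, block, rep) record at row ",
         which(duplicated(key))[1])

  env_levels   <- sort(unique(as.character(data$env)))
  line_levels  <- sort(unique(as.character(data$line)))
  block_levels <- sort(unique(as.character(data$block)))
  I <- length(env_levels); J <- length(line_levels); K <- length(block_levels)

  out <- data.frame(
    env   = as.character(data$env),
    block = as.character(data$block),
    line  = as.character(data$line),
    rep   = data$rep,
    count = as.integer(round(y)),
    stringsAsFactors = FALSE
  )
  out$env_idx   <- match(out$env, env_levels)
  out$line_idx  <- match(out$line, line_levels)
  out$block_idx <- match(out$block, block_levels)
  out$cell_idx  <- (out$env_idx - 1L) * J + out$line_idx
  ord <- order(out$env_idx, out$line_idx, out$block_idx, out$rep)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  structure(out,
            I = I, J = J, K = K, n_T = nrow(out),
            env_levels = env_levels, line_levels = line_levels,
            block_levels = block_levels,
            class = c("bmnb_panel", "data.frame"))
}

#' @export
print.bmnb_panel <- function(x, ...) {
  cat(sprintf("bmnb count panel: %d records, %d environments x %d lines x %d blocks\n",
              attr(x, "n_T"), attr(x, "I"), attr(x, "J"), attr(x, "K")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Genomic relationship matrix from binary marker codes
#'
#' Computes the GRM `G1 = W W' / q` from a lines-by-markers matrix of 0/1
#' allele codes, exactly as printed (no allele-frequency centering by
#' default).  An optional column-centered variant is available.
#'
#' @param W lines-by-markers numeric matrix with entries in \{0, 1\} and no
#'   missing values (use [maf_filter()] first for raw panels).
#' @param ridge non-negative value added to the diagonal; real marker panels
#'   are often rank-deficient, and a small ridge makes `G1` invertible for the
#'   variance-component update.
#' @param center if `TRUE`, columns of `W` are mean-centered before forming
#'   the cross-product.
#' @return J-by-J symmetric positive (semi-)definite matrix with the line
#'   labels of `W` as dimnames.
#' @export
compute_grm <- function(W, ridge = 0, center = FALSE) {
  W <- as.matrix(W)
  if (ncol(W) < 1L) stop("marker matrix has no markers")
  if (anyNA(W)) stop("marker matrix contains missing values; run maf_filter() first")
  if (!all(W %in% c(0, 1))) stop("marker codes must be 0 or 1")
  if (ridge < 0) stop("'ridge' must be non-negative")
  if (center) W <- sweep(W, 2L, colMeans(W), "-")
  G <- tcrossprod(W) / ncol(W)
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  G <- (G + t(G)) / 2
  if (!is.null(rownames(W))) dimnames(G) <- list(rownames(W), rownames(W))
  G
}

#' Expand a line covariance across independent environments
#'
#' Builds `G2 = I_I (x) G1`, the block-diagonal covariance of the GxE effects
#' under the assumption of independence between environments: block (i, i)
#' equals `G1`, off-diagonal blocks are zero, columns ordered
#' environment-major to match the GxE incidence matrix.
#'
#' @param G1 J-by-J symmetric matrix.
#' @param n_env number of environments I (>= 1).
#' @return IJ-by-IJ block-diagonal matrix.
#' @export
build_g2 <- function(G1, n_env) {
  G1 <- as.matrix(G1)
  if (n_env < 1) stop("'n_env' must be at least 1")
  if (max(abs(G1 - t(G1))) > 1e-8 * max(1, max(abs(G1))))
    stop("'G1' must be symmetric")
  kronecker(diag(n_env), G1)
}

#' Assemble the covariance set for model fitting
#'
#' Packages `G1`, its inverse, and `G2 = I_I (x) G1`.  If `G1` is numerically
#' singular a ridge (default `1e-6`) is added to its diagonal before
#' inversion, with a message.
#'
#' @param G1 J-by-J line covariance (GRM from [compute_grm()], or an identity
#'   for i.i.d. line effects).
#' @param n_env number of environments.
#' @param ridge ridge to apply when `G1` cannot be Cholesky-factorized as
#'   given; set to 0 to forbid.
#' @return object of class `bmnb_covset` with elements `G1`, `G2`, `G1inv`,
#'   `ridge_applied`.
#' @export
covariance_set <- function(G1, n_env, ridge = 1e-6) {
  G1 <- as.matrix(G1)
  ridge_applied <- 0
  ch <- tryCatch(chol(G1), error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge <= 0) stop("'G1' is numerically singular and ridge is disabled")
    message("covariance_set: G1 numerically singular; adding ridge ", ridge)
    G1 <- G1 + diag(ridge, nrow(G1))
    ridge_applied <- ridge
    ch <- chol(G1)
  }
  structure(list(G1 = G1,
                 G2 = build_g2(G1, n_env),
                 G1inv = chol2inv(ch),
                 n_env = as.integer(n_env),
                 ridge_applied = ridge_applied),
            class = "bmnb_covset")
}

#' Build the fixed-effect and incidence matrices
#'
#' Constructs the design for the linear predictor
#' `eta = X beta + Z1 b1 + Z2 b2`: `X` holds I environment indicator columns
#' plus, when `include_blocks`, I*K block-within-environment indicator columns
#' (`p = I + I*K`); `Z1` maps each record to its line; `Z2` is the row-wise
#' (face-splitting) product of the environment columns of `X` with `Z1`,
#' giving the n_T-by-IJ incidence of the GxE effects, columns
#' environment-major to match `G2`.
#'
#' With a flat prior on the fixed effects the cell-means environment columns
#' plus a full set of block indicators are collinear; `drop_last_block` drops
#' the last block column of each environment to restore full column rank.
#'
#' @param panel a [count_panel()].
#' @param include_blocks model block-within-environment effects?
#' @param drop_last_block drop one block column per environment (needed under
#'   a flat fixed-effect prior).
#' @return object of class `bmnb_design`: matrices `X`, `Z1`, `Z2`, the
#'   integer index vectors used by the sampler, and the dimensions.
#' @export
build_design <- function(panel, include_blocks = TRUE, drop_last_block = FALSE) {
  stopifnot(inherits(panel, "bmnb_panel"))
  I <- attr(panel, "I"); J <- attr(panel, "J"); K <- attr(panel, "K")
  n_T <- attr(panel, "n_T")
  ei <- panel$env_idx; li <- panel$line_idx; bi <- panel$block_idx
  ci <- panel$cell_idx

  Xenv <- matrix(0, n_T, I)
  Xenv[cbind(seq_len(n_T), ei)] <- 1
  colnames(Xenv) <- paste0("env", attr(panel, "env_levels"))
  if (include_blocks) {
    keepK <- if (drop_last_block) K - 1L else K
    if (keepK < 1L) {
      Xblk <- NULL
    } else {
      Xblk <- matrix(0, n_T, I * keepK)
      keep <- bi <= keepK
      col <- (ei - 1L) * keepK + bi
      Xblk[cbind(which(keep), col[keep])] <- 1
      colnames(Xblk) <- paste0("env", rep(attr(panel, "env_levels"), each = keepK),
                               ".blk", rep(attr(panel, "block_levels")[seq_len(keepK)], I))
    }
    X <- cbind(Xenv, Xblk)
  } else {
    X <- Xenv
  }

  Z1 <- matrix(0, n_T, J)
  Z1[cbind(seq_len(n_T), li)] <- 1
  colnames(Z1) <- attr(panel, "line_levels")
  Z2 <- matrix(0, n_T, I * J)
  Z2[cbind(seq_len(n_T), ci)] <- 1
  colnames(Z2) <- paste0("env", rep(attr(panel, "env_levels"), each = J),
                         ".", rep(attr(panel, "line_levels"), I))

  structure(list(X = X, Z1 = Z1, Z2 = Z2,
                 env_idx = ei, line_idx = li, block_idx = bi, cell_idx = ci,
                 p = ncol(X), I = I, J = J, K = K, n_T = n_T,
                 include_blocks = include_blocks,
                 n_env_cols = I),
            class = "bmnb_design")
}

#' Filter raw markers by minor-allele frequency and missingness
#'
#' Drops markers whose minor-allele frequency (computed over non-missing
#' calls) is below `maf_threshold` or whose fraction of missing calls exceeds
#' `max_missing`; remaining missing entries are imputed to the marker's modal
#' code.  Standard marker preprocessing states the two filters but no imputation
#' rule; modal imputation is this package's minimal-assumption default and is
#' reported via a message.
#'
#' @param W lines-by-markers matrix with entries 0, 1 or `NA`.
#' @param maf_threshold minimum minor-allele frequency, in `[0, 0.5]`.
#' @param max_missing maximum tolerated missing fraction per marker.
#' @return filtered, imputed 0/1 matrix (possibly with zero columns).
#' @export
maf_filter <- function(W, maf_threshold = 0.05, max_missing = 0.10) {
  W <- as.matrix(W)
  if (maf_threshold < 0 || maf_threshold > 0.5)
    stop("'maf_threshold' must be in [0, 0.5]")
  ok <- W %in% c(0, 1) | is.na(W)
  if (!all(ok)) stop("marker codes must be 0, 1 or NA")
  miss_frac <- colMeans(is.na(W))
  p <- colMeans(W, na.rm = TRUE)
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  keep <- miss_frac <= max_missing & maf >= maf_threshold
  out <- W[, keep, drop = FALSE]
  n_imputed <- sum(is.na(out))
  if (n_imputed > 0) {
    for (m in which(colSums(is.na(out)) > 0)) {
      modal <- as.numeric(mean(out[, m], na.rm = TRUE) >= 0.5)
      out[is.na(out[, m]), m] <- modal
    }
  }
  message(sprintf("maf_filter: kept %d of %d markers; imputed %d missing calls to modal code",
                  ncol(out), ncol(W), n_imputed))
  out
}
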