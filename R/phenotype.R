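#' Principal components analysis on the correlation matrix
#'
#' Standardizes each trait, eigendecomposes the correlation matrix, and
#' returns loadings (sign convention: the largest-magnitude loading of each
#' component is positive), scores of the complete cases, and eigenvalues.
#'
#' @param traits Numeric matrix or data frame of continuous traits
#'   (>= 2 columns); rows with any missing value are dropped (>= 3 must
#'   remain).
#' @return List with `loadings`, `scores`, `eigenvalues`,
#'   `explained` (proportions of variance).
#' @export
pca_correlation <- function(traits) {
  x <- as.matrix(traits)
  if (ncol(x) < 2) stop("need at least 2 traits", call. = FALSE)
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant trait(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  r <- cor(x)
  e <- eigen(r, symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- scale(x) %*% load
  list(loadings = load, scores = scores, eigenvalues = e$values,
       explained = e$values / sum(e$values))
}

#' Regress phenotypic traits on ancestry at a spatial extent
#'
#' Ordinary least squares of each trait on the Q-score within the chosen
#' subset: `"all"` specimens, the hybrid `"transect"`, or the `"core"`
#' hybrid zone (logical columns `transect` and `core` in the table mark
#' membership). Missing trait values are handled complete-case per trait.
#' Significance stars follow the usual convention: `*` < 0.05, `**` < 0.01,
#' `***` < 0.001, `ns` otherwise.
#'
#' @param table Phenotype table with `q_score`, trait columns, and logical
#'   `transect`/`core` columns.
#' @param extent One of `"all"`, `"transect"`, `"core"`.
#' @param traits Trait column names; defaults to every numeric column other
#'   than `q_score`.
#' @return Tibble with `trait`, `extent`, `n`, `r_squared`, `p_value`,
#'   `stars` (`ns` with a degenerate note when Q does not vary).
#' @export
regress_traits_on_q <- function(table, extent = c("all", "transect", "core"),
                                traits = NULL) {
  extent <- match.arg(extent)
  sub <- switch(extent,
                all = table,
                transect = table[which(table$transect), , drop = FALSE],
                core = table[which(table$core), , drop = FALSE])
  if (nrow(sub) < 3) stop("fewer than 3 rows at extent '", extent, "'", call. = FALSE)
  if (is.null(traits)) {
    num <- vapply(sub, is.numeric, TRUE)
    traits <- setdiff(names(sub)[num], c("q_score"))
  }
  rows <- lapply(traits, function(tr) {
    d <- sub[!is.na(sub[[tr]]) & !is.na(sub$q_score), c(tr, "q_score")]
    n <- nrow(d)
    if (n < 3)
      return(tibble(trait = tr, extent = extent, n = n, r_squared = NA_real_,
                    p_value = NA_real_, stars = "ns", note = "too few rows"))
    if (var(d$q_score) == 0)
      return(tibble(trait = tr, extent = extent, n = n, r_squared = NA_real_,
                    p_value = NA_real_, stars = "ns", note = "degenerate: Q constant"))
    fit <- lm(d[[tr]] ~ d$q_score)
    sm <- summary(fit)
    p <- sm$coefficients[2, 4]
    tibble(trait = tr, extent = extent, n = n, r_squared = sm$r.squared,
           p_value = p, stars = p_stars(p), note = "")
  })
  do.call(rbind, rows)
}

p_stars <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Trait-by-extent regression table
#'
#' Convenience wrapper building the full trait x spatial-extent R-squared
#' table from one phenotype table.
#'
#' @inheritParams regress_traits_on_q
#' @export
phenotype_assoc_table <- function(table, traits = NULL) {
  do.call(rbind, lapply(c("all", "transect", "core"), function(e)
    regress_traits_on_q(table, e, traits)))
}
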