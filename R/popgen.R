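# Population genetics on cohort callsets: dosage genotype matrices with MAF
# filtering, Weir-Cockerham (1984) per-site F_ST variance components for a
# focal population against all remaining donors pooled, and genotype PCA.

#' Build a donor x site dosage genotype matrix from callsets
#'
#' Alt-allele dosage coding (0/1/2, NA for missing). Masked records and
#' indels are excluded; multi-allelic sites are decomposed into one
#' biallelic site per alt allele (or dropped). Donors without a record at a
#' site score 0 where their diploid assembly spans the position and NA
#' elsewhere. Sites are kept when the minor-allele frequency over non-missing
#' entries exceeds `maf_filter` (strictly, by default; set `inclusive` for >=).
#'
#' @param callsets named list of `callset`s, one per donor.
#' @param mask optional data.frame(start, end); records inside are excluded
#'   even if not flagged masked.
#' @param maf_filter minor-allele-frequency threshold (default 0.05).
#' @param inclusive use MAF >= threshold instead of strict >.
#' @param multiallelic "decompose" (default) or "drop".
#' @return object of class `genotype_matrix`: `G` (donors x sites), `sites`
#'   data.frame(pos, ref, alt, maf).
#' @export
build_genotype_matrix <- function(callsets, mask = NULL, maf_filter = 0.05,
                                  inclusive = FALSE,
                                  multiallelic = c("decompose", "drop")) {
  multiallelic <- match.arg(multiallelic)
  donors <- names(callsets)
  if (is.null(donors) || anyDuplicated(donors))
    stop("callsets must be uniquely named by donor", call. = FALSE)
  site_key <- list()
  for (d in donors) {
    r <- callsets[[d]]$records
    r <- r[r$type == "snv" & !r$masked, , drop = FALSE]
    if (!is.null(mask)) r <- r[!in_intervals(r$pos, mask), , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      alts <- strsplit(r$alt[i], ",", fixed = TRUE)[[1]]
      if (length(alts) > 1L && multiallelic == "drop") next
      for (a in alts)
        site_key[[paste(r$pos[i], a)]] <- c(r$pos[i], r$ref[i], a)
    }
  }
  if (length(site_key) == 0L)
    return(structure(list(G = matrix(numeric(), nrow = length(donors), ncol = 0L,
                                     dimnames = list(donors, NULL)),
                          sites = data.frame(pos = integer(), ref = character(),
                                             alt = character(), maf = numeric())),
                     class = "genotype_matrix"))
  sites <- data.frame(pos = as.integer(vapply(site_key, `[`, "", 1)),
                      ref = vapply(site_key, `[`, "", 2),
                      alt = vapply(site_key, `[`, "", 3), stringsAsFactors = FALSE)
  ord <- order(sites$pos, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  G <- matrix(NA_real_, nrow = length(donors), ncol = nrow(sites),
              dimnames = list(donors, paste0(sites$pos, sites$alt)))
  for (di in seq_along(donors)) {
    cs <- callsets[[donors[di]]]
    r <- cs$records
    span <- cs$diploid_span
    covered <- sites$pos %in% span
    G[di, covered] <- 0
    hit <- match(sites$pos, r$pos)
    for (si in which(!is.na(hit))) {
      rec <- r[hit[si], ]
      if (rec$masked || rec$type != "snv") { G[di, si] <- NA_real_; next }
      alts <- strsplit(rec$alt, ",", fixed = TRUE)[[1]]
      ai <- match(sites$alt[si], alts)
      gt <- strsplit(rec$gt, "/", fixed = TRUE)[[1]]
      if (any(gt == ".")) { G[di, si] <- NA_real_; next }
      if (!is.na(ai)) G[di, si] <- sum(gt == as.character(ai))
      else if (all(gt %in% c("0"))) G[di, si] <- 0
      else G[di, si] <- sum(gt != "0" & gt != ".") * 0  # other-alt carriers: 0 for this alt
    }
  }
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- if (inclusive) maf >= maf_filter else maf > maf_filter
  keep[is.na(keep)] <- FALSE
  structure(list(G = G[, keep, drop = FALSE],
                 sites = cbind(sites[keep, , drop = FALSE], maf = maf[keep])),
            class = "genotype_matrix")
}

# Weir & Cockerham (1984) per-site variance components for r groups from
# per-group (n, p, h): sample size in diploid individuals, alt allele
# frequency, observed heterozygote frequency.
wc_components <- function(n, p, h) {
  r <- length(n)
  nsum <- sum(n)
  nbar <- nsum / r
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  pbar <- sum(n * p) / nsum
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, nbar = nbar, nc = nc, pbar = pbar, hbar = hbar)
}

#' Per-site Weir-Cockerham F_ST, one population against the rest
#'
#' The focal population is compared with all remaining donors pooled as a
#' single second group (r = 2). Sites monomorphic in the combined sample, or
#' with either group empty, are undefined (theta = NA) and excluded from
#' summaries.
#'
#' @param gm a `genotype_matrix` (or plain dosage matrix donors x sites).
#' @param labels data.frame(donor, population) or named vector.
#' @param focal focal population label.
#' @param threshold report count of sites with theta exceeding this
#'   (default 0.3).
#' @return object of class `fst_result`: `per_site` data.frame (a, b, c,
#'   nbar, nc, pbar, hbar, theta per site), `mean_theta` (ratio-of-sums
#'   estimator), `n_exceeding`, `focal`.
#' @export
wc_fst <- function(gm, labels, focal, threshold = 0.3) {
  G <- if (inherits(gm, "genotype_matrix")) gm$G else gm
  sites <- if (inherits(gm, "genotype_matrix")) gm$sites else
    data.frame(pos = seq_len(ncol(G)))
  pops <- if (is.data.frame(labels))
    stats::setNames(labels$population, labels$donor)[rownames(G)]
  else labels[rownames(G)]
  grp <- ifelse(pops == focal, "focal", "rest")
  if (!any(grp == "focal")) stop("focal population empty", call. = FALSE)
  if (!any(grp == "rest")) stop("no donors outside the focal population", call. = FALSE)
  out <- matrix(NA_real_, nrow = ncol(G), ncol = 8L,
                dimnames = list(NULL, c("a", "b", "c", "nbar", "nc", "pbar",
                                        "hbar", "theta")))
  for (s in seq_len(ncol(G))) {
    x <- G[, s]
    ok <- !is.na(x)
    if (!any(ok)) next
    n <- c(sum(ok & grp == "focal"), sum(ok & grp == "rest"))
    if (any(n == 0L)) next
    p <- c(mean(x[ok & grp == "focal"]) / 2, mean(x[ok & grp == "rest"]) / 2)
    h <- c(mean(x[ok & grp == "focal"] == 1), mean(x[ok & grp == "rest"] == 1))
    if (sum(n * p) == 0 || sum(n * p) == sum(n)) next   # monomorphic overall
    comp <- wc_components(n, p, h)
    denom <- comp["a"] + comp["b"] + comp["c"]
    theta <- if (denom == 0) NA_real_ else comp["a"] / denom
    out[s, ] <- c(comp, theta)
  }
  per_site <- cbind(sites, as.data.frame(out))
  defined <- !is.na(per_site$theta)
  mean_theta <- if (any(defined))
    sum(per_site$a[defined]) /
      sum(per_site$a[defined] + per_site$b[defined] + per_site$c[defined])
  else NA_real_
  structure(list(per_site = per_site, mean_theta = mean_theta,
                 n_exceeding = sum(per_site$theta > threshold, na.rm = TRUE),
                 threshold = threshold, focal = focal),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<wc_fst %s vs rest: %d defined sites, mean theta %.4f, %d > %.2f>\n",
              x$focal, sum(!is.na(x$per_site$theta)), x$mean_theta,
              x$n_exceeding, x$threshold))
  invisible(x)
}

#' PCA of a genotype matrix
#'
#' Missing entries are mean-imputed, columns centered at twice the allele
#' frequency and scaled by sqrt(p(1-p)); monomorphic columns are dropped.
#' Decomposition by SVD; scores are returned in decreasing variance order.
#'
#' @param gm a `genotype_matrix` or dosage matrix.
#' @param n_components number of components to return (default all).
#' @return list: `scores` (donors x components), `explained` (variance
#'   fractions), `n_sites_used`. All-constant matrices return zero
#'   components with a warning.
#' @export
pca_genotypes <- function(gm, n_components = NULL) {
  G <- if (inherits(gm, "genotype_matrix")) gm$G else gm
  if (nrow(G) < 2L) stop("need at least two donors", call. = FALSE)
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) {
    warning("no polymorphic sites; zero components")
    return(list(scores = matrix(0, nrow(G), 0L, dimnames = list(rownames(G), NULL)),
                explained = numeric(), n_sites_used = 0L))
  }
  X <- G[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- 2 * p[j]
  }
  X <- sweep(X, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  sv <- svd(X)
  k <- min(n_components %||% length(sv$d), length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       n_sites_used = ncol(X))
}
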