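#' The 12-compartment subcellular localization vocabulary
#'
#' @format character vector of 12 site names.
#' @export
LOCALIZATION_SITES <- c(
  "cytoplasm", "mitochondria", "nucleus", "plasma membrane", "centriole",
  "cytoskeleton", "endoplasmic reticulum", "extracell", "Golgi apparatus",
  "lysosome", "microsome", "peroxisome")

neighbor_sets <- function(net) {
  nb <- vector("list", length(net$nodes))
  names(nb) <- net$nodes
  if (nrow(net$edges)) {
    keep <- net$edges$weight > 0
    e <- net$edges[keep, , drop = FALSE]
    half <- split(c(e$to, e$from), c(e$from, e$to))
    nb[names(half)] <- half
  }
  lapply(nb, function(x) if (is.null(x)) character() else x)
}

#' Small-world clustering coefficient of a protein pair
#'
#' Quantifies how unexpectedly many interaction partners two proteins share,
#' as minus the log of the hypergeometric tail probability of observing at
#' least `k = |N(v) ∩ N(u)|` common neighbors when `|N(u)|` partners are
#' drawn at random from the `N` proteins of the network. A value of 0 means
#' no shared neighbors; larger values indicate a cliquish, small-world-like
#' neighborhood around the edge. Computed in log-space so large networks do
#' not underflow.
#'
#' @param net a [ppi_network]
#' @param v,u distinct node identifiers present in `net`
#' @param base log base: `"natural"` (default) or `"log10"`
#' @return nonnegative real
#' @export
small_world_coefficient <- function(net, v, u, base = c("natural", "log10")) {
  base <- match.arg(base)
  if (identical(v, u)) stop("v and u must be distinct")
  if (!(v %in% net$nodes)) stop("node '", v, "' not in network")
  if (!(u %in% net$nodes)) stop("node '", u, "' not in network")
  nb <- neighbor_sets(net)
  sw_from_counts(length(intersect(nb[[v]], nb[[u]])),
                 length(nb[[v]]), length(nb[[u]]), length(net$nodes),
                 base = base)
}

## -log P(X >= k), X ~ Hypergeometric(nv successes, N - nv failures, nu draws)
sw_from_counts <- function(k, nv, nu, N, base = "natural") {
  if (k <= 0L) return(0)
  logp <- stats::phyper(k - 1L, m = nv, n = N - nv, k = nu,
                        lower.tail = FALSE, log.p = TRUE)
  cvu <- -logp
  if (base == "log10") cvu <- cvu / log(10)
  ## guard against -0 / tiny negatives from the tail at k = 0 support edge
  max(cvu, 0)
}

#' Pearson correlation of two expression profiles
#'
#' Population-moment convention: `rho = ((1/m) sum(x y) - mean(x) mean(y)) /
#' (sd_pop(x) sd_pop(y))` with standard deviations computed with divisor `m`.
#' Returns `NA` (a missing-value marker, not an error) when either profile
#' has zero variance.
#'
#' @param x,y numeric vectors of equal length `m >= 2`
#' @return correlation in `[-1, 1]`, or `NA_real_` for degenerate input
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("expression vectors differ in length")
  m <- length(x)
  if (m < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop("expression vectors contain NA")
  sx <- sqrt(mean(x^2) - mean(x)^2)
  sy <- sqrt(mean(y^2) - mean(y)^2)
  if (sx == 0 || sy == 0) {
    message("zero-variance expression profile; correlation undefined")
    return(NA_real_)
  }
  rho <- (mean(x * y) - mean(x) * mean(y)) / (sx * sy)
  min(1, max(-1, rho))
}

#' Construct a subcellular localization table
#'
#' @param sites named list mapping protein id to a character vector of site
#'   names from [LOCALIZATION_SITES]
#' @param compat data.frame or 2-column matrix of unordered compatible site
#'   pairs (a site is always compatible with itself and need not be listed)
#' @return object of class `localization_table`
#' @export
localization_table <- function(sites = list(), compat = NULL) {
  bad <- setdiff(unique(unlist(sites)), LOCALIZATION_SITES)
  if (length(bad))
    stop("unknown localization site(s): ", paste(bad, collapse = ", "))
  pairs <- character()
  if (!is.null(compat) && NROW(compat) > 0) {
    compat <- as.data.frame(compat, stringsAsFactors = FALSE)
    a <- as.character(compat[[1L]]); b <- as.character(compat[[2L]])
    bad <- setdiff(unique(c(a, b)), LOCALIZATION_SITES)
    if (length(bad))
      stop("unknown site(s) in compatibility list: ",
           paste(bad, collapse = ", "))
    pairs <- unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
  }
  structure(list(sites = sites, compat = pairs),
            class = "localization_table")
}

#' @export
print.localization_table <- function(x, ...) {
  cat("Localization table:", length(x$sites), "proteins,",
      length(x$compat), "compatible site pairs\n")
  invisible(x)
}

#' Read a localization table from TSV files
#'
#' The localization file has two tab-separated columns: protein id and a
#' semicolon-separated list of site names. The compatibility file has two
#' tab-separated site-name columns, one compatible pair per line.
#'
#' @param path localization TSV
#' @param compat_path site-compatibility TSV (optional)
#' @return a [localization_table]
#' @export
read_localization <- function(path, compat_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("localization file must have 2 tab-separated columns")
  sites <- lapply(parts, function(p) trimws(strsplit(p[2L], ";")[[1L]]))
  names(sites) <- vapply(parts, `[`, "", 1L)
  compat <- NULL
  if (!is.null(compat_path)) {
    cl <- readLines(compat_path)
    cl <- cl[!startsWith(trimws(cl), "#") & nzchar(trimws(cl))]
    cp <- strsplit(cl, "\t", fixed = TRUE)
    if (any(lengths(cp) != 2L))
      stop("compatibility file must have 2 tab-separated columns")
    compat <- data.frame(a = vapply(cp, `[`, "", 1L),
                         b = vapply(cp, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  }
  localization_table(sites, compat)
}

#' Localization compatibility of two proteins
#'
#' Returns 1 if any annotated site of `v` and any site of `u` form a
#' compatible pair (every site is compatible with itself); 0 otherwise,
#' including when either protein lacks a localization record.
#'
#' @param locs a [localization_table]
#' @param v,u protein identifiers
#' @return 0 or 1
#' @export
localization_compat <- function(locs, v, u) {
  sv <- locs$sites[[v]]
  su <- locs$sites[[u]]
  if (is.null(sv) || is.null(su) || !length(sv) || !length(su)) {
    message("no localization record for ",
            if (is.null(sv) || !length(sv)) v else u)
    return(0L)
  }
  if (length(intersect(sv, su))) return(1L)
  grid <- expand.grid(a = sv, b = su, stringsAsFactors = FALSE)
  keys <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b), sep = "|")
  as.integer(any(keys %in% locs$compat))
}

#' Read a gene expression matrix from TSV
#'
#' First column: gene id; remaining columns: real-valued samples; one header
#' row of sample names.
#'
#' @param path TSV path
#' @return numeric matrix, genes in rows (rownames), samples in columns
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("expression values must be numeric")
  if (ncol(mat) < 2L) stop("expression matrix needs at least 2 samples")
  rownames(mat) <- as.character(df[[1L]])
  mat
}

#' Compute the per-edge feature triple for a whole network
#'
#' For every edge of `net`, computes the small-world clustering coefficient
#' (from `net`'s own topology), the expression Pearson correlation of the
#' two incident genes, and the binary localization compatibility. Missing
#' expression profiles (or zero-variance ones) are imputed to a neutral
#' correlation of 0 and counted in the returned summary.
#'
#' @param net a [ppi_network]
#' @param expr expression matrix (genes x samples) as from
#'   [read_expression()], or `NULL` to impute all correlations
#' @param locs a [localization_table], or `NULL` to set all compatibilities
#'   to 0
#' @return data.frame with one row per edge and columns `from`, `to`, `C`,
#'   `rho`, `loc`; attribute `"imputed"` holds counts of imputed
#'   correlations and missing localization records
#' @export
build_edge_features <- function(net, expr = NULL, locs = NULL) {
  nb <- neighbor_sets(net)
  N <- length(net$nodes)
  e <- net$edges
  n <- nrow(e)
  C <- numeric(n)
  rho <- numeric(n)
  loc <- integer(n)
  rho_imputed <- 0L
  loc_missing <- 0L
  have_expr <- !is.null(expr)
  if (have_expr) {
    ## center/scale once so each correlation is a dot product
    mu <- rowMeans(expr)
    sd_pop <- sqrt(rowMeans(expr^2) - mu^2)
    usable <- sd_pop > 0
    Z <- (expr - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  }
  for (i in seq_len(n)) {
    v <- e$from[i]; u <- e$to[i]
    C[i] <- sw_from_counts(length(intersect(nb[[v]], nb[[u]])),
                           length(nb[[v]]), length(nb[[u]]), N)
    if (have_expr && v %in% rownames(expr) && u %in% rownames(expr) &&
        usable[v] && usable[u]) {
      r <- mean(Z[v, ] * Z[u, ])
      rho[i] <- min(1, max(-1, r))
    } else {
      rho[i] <- 0
      rho_imputed <- rho_imputed + 1L
    }
    if (!is.null(locs)) {
      sv <- locs$sites[[v]]; su <- locs$sites[[u]]
      if (is.null(sv) || is.null(su) || !length(sv) || !length(su)) {
        loc[i] <- 0L
        loc_missing <- loc_missing + 1L
      } else {
        loc[i] <- suppressMessages(localization_compat(locs, v, u))
      }
    } else {
      loc[i] <- 0L
      loc_missing <- loc_missing + 1L
    }
  }
  out <- data.frame(from = e$from, to = e$to, C = C, rho = rho, loc = loc,
                    stringsAsFactors = FALSE)
  attr(out, "imputed") <- list(rho_imputed = rho_imputed,
                               loc_missing = loc_missing)
  out
}
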