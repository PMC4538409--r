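#' Logistic mapping of disease similarity to a relatedness probability
#'
#' `L(x) = 1 / (1 + exp(c * x + d))` with defaults `c = -15`,
#' `d = log(9999)`, calibrated so that `L(0) = 1e-4` and `L(1) ~ 0.997`:
#' phenotype similarities below about 0.3 (uninformative band) map to nearly
#' zero relatedness while similarities above 0.6 (informative band) approach
#' one.
#'
#' @param x similarity value(s), typically in `[0, 1]`
#' @param c slope parameter (default -15)
#' @param d offset parameter (default `log(9999)`)
#' @return value(s) in `(0, 1)`
#' @export
similarity_logistic <- function(x, c = -15, d = log(9999)) {
  if (any(!is.finite(x))) stop("similarity values must be finite")
  1 / (1 + exp(c * x + d))
}

#' Read a square disease-disease similarity matrix from TSV
#'
#' Disease ids form the first row (header) and first column; entries must be
#' in `[0, 1]`, the matrix symmetric and the diagonal 1.
#'
#' @param path TSV path
#' @return numeric matrix with disease ids as dimnames
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  rownames(S) <- as.character(df[[1L]])
  validate_similarity(S)
  S
}

validate_similarity <- function(S) {
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (!identical(rownames(S), colnames(S)))
    stop("similarity matrix row/column disease ids differ")
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1))
    stop("similarity entries must lie in [0, 1]")
  if (max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8)
    stop("similarity matrix diagonal must be 1")
  invisible(S)
}

#' Read a disease-gene association map from a 2-column TSV
#'
#' @param path TSV with columns `disease_id`, `gene_id`; `#`-prefixed lines
#'   skipped
#' @return data.frame with columns `disease`, `gene`
#' @export
read_associations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) != 2L))
    stop("association file must have 2 columns (disease_id, gene_id)")
  data.frame(disease = vapply(parts, `[`, "", 1L),
             gene = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Build the disease-similarity prior vector for a query disease
#'
#' For every protein `v` of the network, `Y(v) = L(max_p S(q, p))` over the
#' diseases `p` that `v` is associated with (so a protein associated with
#' the query itself receives `L(1)` via the unit diagonal), and `Y(v) = 0`
#' for proteins with no disease association. Taking the maximum over
#' associated diseases follows the most-similar-disease selection rule of
#' prior label-propagation prioritizers.
#'
#' @param S similarity matrix as from [read_similarity_matrix()]
#' @param q query disease id (must be a row of `S`)
#' @param assoc association data.frame (`disease`, `gene`) as from
#'   [read_associations()]
#' @param net a [ppi_network] fixing the node order of the result
#' @param c,d logistic parameters passed to [similarity_logistic()]
#' @return named numeric vector `Y` over `net$nodes`, entries in `[0, 1)`
#' @export
build_prior <- function(S, q, assoc, net, c = -15, d = log(9999)) {
  validate_similarity(S)
  if (!(q %in% rownames(S)))
    stop("query disease '", q, "' absent from similarity matrix")
  assoc <- assoc[assoc$disease %in% rownames(S), , drop = FALSE]
  unresolved <- setdiff(unique(assoc$gene), net$nodes)
  if (length(unresolved)) {
    warning(length(unresolved),
            " associated gene(s) not in the network dropped")
    assoc <- assoc[assoc$gene %in% net$nodes, , drop = FALSE]
  }
  Y <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(assoc)) {
    sim <- S[q, assoc$disease]
    smax <- tapply(sim, assoc$gene, max)
    Y[names(smax)] <- similarity_logistic(as.numeric(smax), c = c, d = d)
  }
  Y
}
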