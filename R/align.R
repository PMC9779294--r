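#' Alignment parameters
#'
#' Defaults follow common practice for global protein alignment: BLOSUM62
#' substitution scores with affine gap penalties. A gap of length `k`
#' costs `gap_open + k * gap_extend` (both negative), so the per-position
#' extension cost applies to every gapped position including the first.
#'
#' @param substitution substitution matrix name (`"BLOSUM62"`,
#'   `"BLOSUM45"`, `"BLOSUM100"`, `"PAM30"`, `"PAM70"`, `"PAM250"`) or a
#'   symmetric numeric matrix with amino-acid dimnames.
#' @param gap_open gap opening penalty (negative).
#' @param gap_extend gap extension penalty per gapped position (negative).
#' @return list of class `align_params`.
#' @export
align_params <- function(substitution = "BLOSUM62", gap_open = -10,
                         gap_extend = -1) {
  if (is.character(substitution)) {
    env <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = env)
    substitution <- get(substitution, envir = env)
  }
  stopifnot(is.matrix(substitution), gap_open <= 0, gap_extend <= 0)
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch / Gotoh dynamic programming over the full lengths of
#' both sequences (end gaps penalized). The traceback is deterministic:
#' ties are broken by preferring a substitution column, then a gap in the
#' query, then a gap in the reference, so identical inputs always give the
#' identical alignment.
#'
#' @param ref,query named length-1 character vectors or plain strings over
#'   the 20-letter amino-acid alphabet; names (if present) become the
#'   alignment's sequence ids.
#' @param params an [align_params] object.
#' @return object of class `pairwise_alignment` with elements `ref_id`,
#'   `query_id`, `aligned_ref`, `aligned_query` (gapped strings of equal
#'   length), `score`, and `column_map` (two-column matrix of ref/query
#'   positions per column, `NA` at gaps).
#' @examples
#' aln <- global_align(c(E2 = "MVAGMLGLR"), c(E1 = "MAAAR"))
#' aln$score
#' @export
global_align <- function(ref, query, params = align_params()) {
  ref_id <- names(ref) %||% "ref"
  query_id <- names(query) %||% "query"
  r <- .check_aa(unname(ref))
  q <- .check_aa(unname(query))
  sub <- params$substitution
  go <- params$gap_open
  ge <- params$gap_extend
  n <- length(r); m <- length(q)
  ri <- match(r, rownames(sub)); qi <- match(q, colnames(sub))
  NEG <- -1e18

  ## state matrices: M substitution, X gap in query (ref consumed),
  ## Y gap in ref (query consumed); rows 0..n, cols 0..m
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n) X[2L:(n + 1L), 1L] <- go + ge * seq_len(n)
  if (m) Y[1L, 2L:(m + 1L)] <- go + ge * seq_len(m)

  if (n && m) {
    js <- 2L:(m + 1L)
    for (i in 2L:(n + 1L)) {
      prevM <- M[i - 1L, ]; prevX <- X[i - 1L, ]; prevY <- Y[i - 1L, ]
      s <- sub[ri[i - 1L], qi]
      M[i, js] <- pmax(prevM[js - 1L], prevX[js - 1L], prevY[js - 1L]) + s
      X[i, js] <- pmax(prevM[js] + go, prevX[js], prevY[js] + go) + ge
      ## Y along the row via running-max of (best-so-far + go - k*ge)
      z <- pmax(M[i, ], X[i, ]) + go - ge * (0:m)
      Y[i, js] <- ge * (1:m) + cummax(z[-(m + 1L)])
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  ## deterministic traceback (prefer M, then X, then Y)
  state <- c("M", "X", "Y")[which.max(c(M[n + 1L, m + 1L],
                                        X[n + 1L, m + 1L],
                                        Y[n + 1L, m + 1L]))]
  i <- n; j <- m
  cols_ref <- integer(0); cols_query <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      cols_ref <- c(i, cols_ref); cols_query <- c(j, cols_query)
      vals <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which.max(vals)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      cols_ref <- c(i, cols_ref); cols_query <- c(NA_integer_, cols_query)
      cur <- X[i + 1L, j + 1L]
      state <- if (M[i, j + 1L] + go + ge == cur) "M"
               else if (X[i, j + 1L] + ge == cur) "X" else "Y"
      i <- i - 1L
    } else {
      cols_ref <- c(NA_integer_, cols_ref); cols_query <- c(j, cols_query)
      cur <- Y[i + 1L, j + 1L]
      state <- if (M[i + 1L, j] + go + ge == cur) "M"
               else if (X[i + 1L, j] + go + ge == cur) "X" else "Y"
      j <- j - 1L
    }
  }
  aligned_ref <- ifelse(is.na(cols_ref), "-", r[cols_ref])
  aligned_query <- ifelse(is.na(cols_query), "-", q[cols_query])
  structure(list(ref_id = ref_id, query_id = query_id,
                 aligned_ref = paste(aligned_ref, collapse = ""),
                 aligned_query = paste(aligned_query, collapse = ""),
                 score = score,
                 column_map = cbind(ref = cols_ref, query = cols_query)),
            class = "pairwise_alignment")
}

.check_aa <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop("sequence is empty")
  v <- strsplit(toupper(x), "")[[1L]]
  bad <- setdiff(unique(v), .aa_alphabet)
  if (length(bad))
    stop("non-amino-acid symbol(s): ", paste(bad, collapse = ", "))
  v
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat("pairwise_alignment: ", x$ref_id, " vs ", x$query_id,
      "  score = ", x$score, "\n", sep = "")
  a <- strsplit(x$aligned_ref, "")[[1L]]
  b <- strsplit(x$aligned_query, "")[[1L]]
  for (s in seq(1L, length(a), by = width)) {
    e <- min(s + width - 1L, length(a))
    cat("  ", paste(a[s:e], collapse = ""), "\n", sep = "")
    cat("  ", paste(ifelse(a[s:e] == b[s:e] & a[s:e] != "-", "|", " "),
                    collapse = ""), "\n", sep = "")
    cat("  ", paste(b[s:e], collapse = ""), "\n\n", sep = "")
  }
  invisible(x)
}

#' Identical-column positions of an alignment
#'
#' Returns the reference positions whose aligned query residue is
#' identical, optionally restricted to "anchored" runs of at least
#' `min_anchor` consecutive identical columns. Anchoring discounts chance
#' identities inside divergent (novel or alternative-terminus) blocks so a
#' clean truncation is not misread as an internal gap.
#'
#' @param aln a `pairwise_alignment`.
#' @param min_anchor minimum run length of identical columns for a match
#'   to count; `1` disables anchoring.
#' @return integer vector of matched reference positions.
#' @export
matched_ref_positions <- function(aln, min_anchor = 6L) {
  a <- strsplit(aln$aligned_ref, "")[[1L]]
  b <- strsplit(aln$aligned_query, "")[[1L]]
  ident <- a == b & a != "-"
  if (min_anchor > 1L && any(ident)) {
    runs <- rle(ident)
    runs$values <- runs$values & runs$lengths >= min_anchor
    ident <- inverse.rle(runs)
  }
  aln$column_map[ident, "ref"]
}
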