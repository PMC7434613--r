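# Family alignment: container for an aligned set of paralog protein
# sequences plus the residue <-> alignment-column index maps that make
# positions comparable across genes.

#' Construct a paralog alignment
#'
#' A `paralog_alignment` is a tibble with one row per family member and
#' columns `gene_id`, `transcript_id` and `aligned` (the gapped one-letter
#' sequence), carrying the alignment width and the reference (anchor) gene
#' as attributes. Positions are 1-based throughout: residue positions count
#' ungapped residues within one gene, alignment columns count columns of
#' the family alignment.
#'
#' @param rows Data frame with columns `gene_id`, `aligned` and optionally
#'   `transcript_id`.
#' @param reference_gene Gene symbol used as the coordinate anchor; must be
#'   one of `rows$gene_id`.
#' @return A `paralog_alignment` tibble with attributes `n_columns` and
#'   `reference_gene`.
#' @examples
#' paralog_alignment(
#'   data.frame(gene_id = c("A", "B"), aligned = c("AC-D", "ACED")),
#'   reference_gene = "A"
#' )
#' @export
paralog_alignment <- function(rows, reference_gene) {
  rows <- as_tibble(rows)
  if (!all(c("gene_id", "aligned") %in% names(rows))) {
    stop_format("alignment rows need columns 'gene_id' and 'aligned'")
  }
  if (!"transcript_id" %in% names(rows)) {
    rows$transcript_id <- NA_character_
  }
  rows <- rows[, c("gene_id", "transcript_id", "aligned")]
  if (nrow(rows) < 2) {
    stop_format("an alignment needs at least 2 sequences")
  }
  if (anyDuplicated(rows$gene_id)) {
    dup <- unique(rows$gene_id[duplicated(rows$gene_id)])
    stop_format(paste0("duplicated gene_id in alignment: ", paste(dup, collapse = ", ")))
  }
  widths <- nchar(rows$aligned)
  if (length(unique(widths)) != 1L) {
    stop_format(paste0(
      "ragged alignment: aligned lengths differ (",
      paste(unique(widths), collapse = ", "), ")"
    ))
  }
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "-]+$"), rows$aligned)
  if (any(bad)) {
    stop_alphabet(paste0(
      "illegal character in aligned sequence(s): ",
      paste(rows$gene_id[bad], collapse = ", "),
      " (allowed: the 20 standard amino acids and '-')"
    ))
  }
  if (any(gsub("-", "", rows$aligned) == "")) {
    rlang::warn("alignment contains all-gap row(s)")
  }
  if (missing(reference_gene) || !reference_gene %in% rows$gene_id) {
    stop_reference(paste0(
      "reference gene '", if (missing(reference_gene)) "<missing>" else reference_gene,
      "' is not a row of the alignment"
    ))
  }
  structure(
    rows,
    n_columns = widths[1],
    reference_gene = reference_gene,
    class = c("paralog_alignment", class(tibble()))
  )
}

#' @export
print.paralog_alignment <- function(x, ...) {
  cat(
    "<paralog_alignment> ", nrow(x), " sequences x ", attr(x, "n_columns"),
    " columns (reference: ", attr(x, "reference_gene"), ")\n",
    sep = ""
  )
  NextMethod()
}

#' Number of columns of a paralog alignment
#' @param aln A [paralog_alignment()].
#' @return Integer alignment width.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  attr(aln, "n_columns")
}

#' Ungapped residues of each alignment row
#' @param aln A [paralog_alignment()].
#' @return Named character vector of degapped sequences, one per gene.
#' @export
alignment_residues <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  setNames(gsub("-", "", aln$aligned), aln$gene_id)
}

#' Read an aligned FASTA of gene-family paralogs
#'
#' Headers must follow the `gene|transcript` dialect, e.g.
#' `>SCN9A|ENST00000409672`; anything after the first whitespace is ignored.
#' The gap character is `-`; all records must have equal aligned length.
#'
#' @param file Path to an aligned FASTA file, or the FASTA content itself
#'   (a string containing newlines or a character vector of lines).
#' @param reference_gene Gene symbol to anchor coordinates on; defaults to
#'   the first record's gene.
#' @return A [paralog_alignment()].
#' @export
read_alignment_fasta <- function(file, reference_gene = NULL) {
  is_text <- length(file) > 1L || grepl("\n", file[1]) || startsWith(file[1], ">")
  path <- if (is_text) {
    tf <- tempfile(fileext = ".fasta")
    writeLines(unlist(strsplit(file, "\n")), tf)
    tf
  } else {
    if (!file.exists(file)) stop_format(paste0("alignment file not found: ", file))
    file
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format(paste0("cannot parse FASTA: ", conditionMessage(e)))
  )
  if (length(set) < 2) stop_format("alignment FASTA needs at least 2 records")
  headers <- sub("\\s.*$", "", names(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    bad <- headers[lengths(parts) < 2]
    stop_format(paste0(
      "FASTA header(s) not in 'gene|transcript' form: ",
      paste(bad, collapse = ", ")
    ))
  }
  gene_ids <- vapply(parts, `[`, "", 1L)
  paralog_alignment(
    tibble(
      gene_id = gene_ids,
      transcript_id = vapply(parts, `[`, "", 2L),
      aligned = unname(as.character(set))
    ),
    reference_gene = reference_gene %||% gene_ids[1]
  )
}

#' Write a paralog alignment as aligned FASTA
#'
#' Records are written in row order with `gene|transcript` headers and
#' sequence lines wrapped at 60 columns.
#'
#' @param aln A [paralog_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "paralog_alignment"))
  set <- Biostrings::AAStringSet(aln$aligned)
  tx <- ifelse(is.na(aln$transcript_id), "unknown", aln$transcript_id)
  names(set) <- paste0(aln$gene_id, "|", tx)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Residue/column index map of a paralog alignment
#'
#' For every gene the map links each 1-based residue position of the
#' ungapped sequence to its 1-based alignment column. The two directions are
#' mutually inverse on non-gap positions, and residue positions are strictly
#' increasing with column.
#'
#' @param aln A [paralog_alignment()].
#' @return A tibble with columns `gene_id`, `residue`, `column`, carrying
#'   `n_columns` as an attribute.
#' @examples
#' aln <- paralog_alignment(
#'   data.frame(gene_id = c("A", "B"), aligned = c("--ACED", "GGACED")),
#'   reference_gene = "B"
#' )
#' alignment_index_map(aln)
#' @export
alignment_index_map <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  maps <- purrr::map2(aln$gene_id, aln$aligned, function(g, s) {
    cols <- which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
    tibble(gene_id = g, residue = seq_along(cols), column = cols)
  })
  out <- dplyr::bind_rows(maps)
  attr(out, "n_columns") <- attr(aln, "n_columns")
  out
}

#' Map residue positions to alignment columns
#'
#' @param map An index map from [alignment_index_map()].
#' @param gene Gene symbol(s), recycled against `residue`.
#' @param residue 1-based residue position(s).
#' @return Integer vector of 1-based alignment columns.
#' @export
residue_to_column <- function(map, gene, residue) {
  n <- max(length(gene), length(residue))
  gene <- rep_len(gene, n)
  residue <- rep_len(as.integer(residue), n)
  unknown <- setdiff(unique(gene), unique(map$gene_id))
  if (length(unknown)) {
    stop_coordinate(paste0("gene(s) not in alignment: ", paste(unknown, collapse = ", ")))
  }
  key <- paste(map$gene_id, map$residue)
  idx <- match(paste(gene, residue), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop_coordinate(paste0(
      "residue ", residue[bad], " is beyond the length of ", gene[bad]
    ))
  }
  map$column[idx]
}

#' Map alignment columns back to residue positions
#'
#' @inheritParams residue_to_column
#' @param column 1-based alignment column(s).
#' @return Integer vector of residue positions; `NA` where the gene has a
#'   gap in that column.
#' @export
column_to_residue <- function(map, gene, column) {
  n <- max(length(gene), length(column))
  gene <- rep_len(gene, n)
  column <- rep_len(as.integer(column), n)
  nc <- attr(map, "n_columns")
  if (!is.null(nc) && any(column < 1L | column > nc)) {
    stop_index(paste0("column out of range 1..", nc))
  }
  idx <- match(paste(gene, column), paste(map$gene_id, map$column))
  ifelse(is.na(idx), NA_integer_, map$residue[idx])
}

## ---- progressive aligner (for synthetic families) -------------------------

# Column-vs-column profile score: average pairwise score over all residue
# pairs of the two columns; residue-vs-gap scores `gap`, gap-vs-gap scores 0.
profile_col_score <- function(colA, colB, match, mismatch, gap) {
  tot <- 0
  for (x in colA) {
    for (y in colB) {
      tot <- tot + if (x == "-" && y == "-") {
        0
      } else if (x == "-" || y == "-") {
        gap
      } else if (x == y) {
        match
      } else {
        mismatch
      }
    }
  }
  tot / (length(colA) * length(colB))
}

# Needleman-Wunsch on two profiles (character matrices, one row per
# sequence). Linear gap cost; deterministic tie-breaking diagonal > up >
# left ("up" consumes a column of A, "left" a column of B).
nw_profiles <- function(A, B, match, mismatch, gap) {
  la <- ncol(A)
  lb <- ncol(B)
  gapA <- vapply(seq_len(la), function(i) mean(A[, i] != "-") * gap, numeric(1))
  gapB <- vapply(seq_len(lb), function(j) mean(B[, j] != "-") * gap, numeric(1))
  S <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      S[i, j] <- profile_col_score(A[, i], B[, j], match, mismatch, gap)
    }
  }
  M <- matrix(-Inf, la + 1L, lb + 1L)
  M[1, 1] <- 0
  if (la > 0) M[seq_len(la) + 1L, 1] <- cumsum(gapA)
  if (lb > 0) M[1, seq_len(lb) + 1L] <- cumsum(gapB)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      M[i + 1L, j + 1L] <- max(
        M[i, j] + S[i, j],
        M[i, j + 1L] + gapA[i],
        M[i + 1L, j] + gapB[j]
      )
    }
  }
  # traceback, re-applying the diagonal > up > left precedence
  i <- la
  j <- lb
  steps <- character(0)
  eps <- 1e-9
  while (i > 0 || j > 0) {
    cur <- M[i + 1L, j + 1L]
    if (i > 0 && j > 0 && abs(M[i, j] + S[i, j] - cur) < eps) {
      steps <- c("d", steps)
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0 && abs(M[i, j + 1L] + gapA[i] - cur) < eps) {
      steps <- c("u", steps)
      i <- i - 1L
    } else {
      steps <- c("l", steps)
      j <- j - 1L
    }
  }
  out <- matrix("-", nrow(A) + nrow(B), length(steps))
  ai <- 0L
  bj <- 0L
  for (k in seq_along(steps)) {
    if (steps[k] %in% c("d", "u")) {
      ai <- ai + 1L
      out[seq_len(nrow(A)), k] <- A[, ai]
    }
    if (steps[k] %in% c("d", "l")) {
      bj <- bj + 1L
      out[nrow(A) + seq_len(nrow(B)), k] <- B[, bj]
    }
  }
  list(profile = out, score = M[la + 1L, lb + 1L])
}

#' Progressively align a small family of paralog sequences
#'
#' A deterministic progressive Needleman-Wunsch utility for synthetic
#' families: sequences are merged in input order (the guide order), profile
#' columns are scored as the average pairwise residue score, gaps cost
#' `gap` per residue-vs-gap pair (linear, no separate opening penalty), and
#' dynamic-programming ties are resolved diagonal > up > left. It exists so
#' simulated families can be exercised end-to-end; it does not attempt to
#' reproduce any published alignment.
#'
#' @param seqs Data frame with columns `gene_id`, `residues` and optionally
#'   `transcript_id` (ungapped one-letter sequences).
#' @param match,mismatch,gap Scores for matching, mismatching and
#'   residue-vs-gap column pairs.
#' @param reference_gene Anchor gene for the result; defaults to the first.
#' @return A [paralog_alignment()] with the final merge score in attribute
#'   `"score"` (for two sequences this is the global pairwise score).
#' @examples
#' align_family(data.frame(gene_id = c("A", "B"), residues = c("ACD", "AD")))
#' @export
align_family <- function(seqs, match = 1, mismatch = -1, gap = -1,
                         reference_gene = NULL) {
  seqs <- as_tibble(seqs)
  if (!all(c("gene_id", "residues") %in% names(seqs))) {
    stop_format("align_family() needs columns 'gene_id' and 'residues'")
  }
  if (nrow(seqs) < 2) stop_format("need at least 2 sequences to align")
  if (any(is.na(seqs$residues) | seqs$residues == "")) {
    stop_value("empty sequence in align_family() input")
  }
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs$residues)
  if (any(bad)) {
    stop_alphabet(paste0(
      "illegal character in sequence(s): ",
      paste(seqs$gene_id[bad], collapse = ", ")
    ))
  }
  chars <- lapply(seqs$residues, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  profile <- matrix(chars[[1]], nrow = 1)
  score <- NA_real_
  for (k in 2:nrow(seqs)) {
    merged <- nw_profiles(
      profile, matrix(chars[[k]], nrow = 1),
      match = match, mismatch = mismatch, gap = gap
    )
    profile <- merged$profile
    score <- merged$score
  }
  aligned <- apply(profile, 1, paste, collapse = "")
  out <- paralog_alignment(
    tibble(
      gene_id = seqs$gene_id,
      transcript_id = if ("transcript_id" %in% names(seqs)) seqs$transcript_id else NA_character_,
      aligned = aligned
    ),
    reference_gene = reference_gene %||% seqs$gene_id[1]
  )
  attr(out, "score") <- score
  out
}
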