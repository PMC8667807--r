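#' Default anchoring configuration
#'
#' Scoring and guard parameters for [align_global()] and
#' [anchor_filter_residue()]: match reward, mismatch penalty, linear gap
#' penalty (end gaps included), the identity floor below which an anchor is
#' flagged low-confidence, and the query length cap. A plain `key = value`
#' config file can override any of them.
#'
#' @param path Optional path to a `key = value` text file overriding
#'   defaults (keys: `match`, `mismatch`, `gap`, `identity_floor`,
#'   `length_cap`).
#' @return Named list of parameters.
#' @export
#' @examples
#' anchor_config()
anchor_config <- function(path = NULL) {
  cfg <- list(match = 1L, mismatch = -1L, gap = -2L,
              identity_floor = 0.30, length_cap = 2000L)
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        stop("malformed config line: '", ln, "' (expected key = value)",
             call. = FALSE)
      }
      key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
      if (!key %in% names(cfg)) {
        stop("unknown config key '", key, "'", call. = FALSE)
      }
      cfg[[key]] <- if (key == "identity_floor") val else as.integer(val)
    }
  }
  cfg
}

.AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read amino-acid sequences from FASTA
#'
#' Reads a multi-record FASTA file and validates it strictly: ids are the
#' header up to the first whitespace and must be unique; sequences must be
#' non-empty and use only the 20 standard one-letter codes (ambiguity codes
#' such as B, Z, X are rejected, with the offending record and in-sequence
#' position reported). Input order is preserved.
#'
#' @param source Path to a FASTA file.
#' @return A data.frame with columns `id` and `residues`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">q1 test", "GALTSSAMWFSNVLLNSGIGE"), fa)
#' read_fasta(fa)
read_fasta <- function(source) {
  if (!file.exists(source)) {
    stop("FASTA file not found: ", source, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(source),
    error = function(e) stop("cannot parse FASTA '", source, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file '", source, "' contains no records", call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) {
      stop("record '", ids[k], "' has an empty sequence", call. = FALSE)
    }
    chars <- strsplit(seqs[k], "")[[1]]
    bad <- which(!chars %in% .AA_STANDARD)
    if (length(bad)) {
      stop("record '", ids[k], "': illegal residue '", chars[bad[1]],
           "' at sequence position ", bad[1], call. = FALSE)
    }
  }
  data.frame(id = ids, residues = unname(seqs), stringsAsFactors = FALSE)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with the configured scoring (default match +1,
#' mismatch -1, linear gap -2; end gaps penalized). Traceback ties are
#' broken with the fixed move precedence diagonal > up (gap in reference) >
#' left (gap in query), so alignments — and hence anchored coordinates —
#' are bit-reproducible.
#'
#' @param query A single sequence string, or a one-row [read_fasta()]
#'   record.
#' @param reference Reference amino-acid string.
#' @param config See [anchor_config()].
#' @return A `global_alignment`: list with `score` (integer) and `map`, a
#'   data.frame of alignment columns with 1-based `qpos`/`rpos` (`NA` at a
#'   gap) and the aligned characters `qchar`/`rchar` (`"-"` at a gap).
#' @export
#' @examples
#' align_global("GATTACA", "GATTA")$score
align_global <- function(query, reference, config = anchor_config()) {
  q <- .as_seq_string(query)
  r <- reference
  stopifnot(is.character(r), length(r) == 1L)
  if (!nzchar(q) || !nzchar(r)) {
    stop("alignment requires two non-empty sequences", call. = FALSE)
  }
  if (nchar(q) > config$length_cap || nchar(r) > config$length_cap) {
    stop("sequence exceeds the configured length cap (", config$length_cap,
         "); truncate the query to the M2 region before anchoring",
         call. = FALSE)
  }
  qs <- strsplit(toupper(q), "")[[1]]
  rs <- strsplit(toupper(r), "")[[1]]
  n <- length(qs); m <- length(rs)
  gap <- config$gap

  F <- matrix(0L, n + 1L, m + 1L)
  F[, 1L] <- gap * 0:n
  F[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub_row <- ifelse(rs == qs[i], config$match, config$mismatch)
    for (j in seq_len(m)) {
      F[i + 1L, j + 1L] <- max(F[i, j] + sub_row[j],
                               F[i, j + 1L] + gap,
                               F[i + 1L, j] + gap)
    }
  }

  # traceback, precedence diagonal > up > left
  i <- n; j <- m
  qpos <- integer(0); rpos <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] ==
          F[i, j] + (if (qs[i] == rs[j]) config$match else config$mismatch)) {
      qpos <- c(i, qpos); rpos <- c(j, rpos); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      qpos <- c(i, qpos); rpos <- c(NA_integer_, rpos); i <- i - 1L
    } else {
      qpos <- c(NA_integer_, qpos); rpos <- c(j, rpos); j <- j - 1L
    }
  }
  map <- data.frame(
    qpos = qpos, rpos = rpos,
    qchar = ifelse(is.na(qpos), "-", qs[ifelse(is.na(qpos), 1L, qpos)]),
    rchar = ifelse(is.na(rpos), "-", rs[ifelse(is.na(rpos), 1L, rpos)]),
    stringsAsFactors = FALSE
  )
  structure(list(score = F[n + 1L, m + 1L], map = map),
            class = "global_alignment")
}

.as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "residues" %in% names(x))
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global alignment> score %d over %d columns\n",
              x$score, nrow(x$map)))
  cat(" ", paste(x$map$qchar, collapse = ""), "\n")
  cat(" ", paste(ifelse(!is.na(x$map$qpos) & !is.na(x$map$rpos) &
                          x$map$qchar == x$map$rchar, "|", " "),
                 collapse = ""), "\n")
  cat(" ", paste(x$map$rchar, collapse = ""), "\n")
  invisible(x)
}

#' Anchor the selectivity-filter residue in a query sequence
#'
#' Aligns the query globally against a registry subunit's M2 reference
#' fragment and projects the fragment's filter column into query
#' coordinates, reporting the query residue found there. This is the
#' single-query stand-in for a multiple alignment of the subunit family:
#' one pairwise alignment per query against a short reference.
#'
#' Flags: `NO_HOMOLOGOUS_RESIDUE` when the filter column aligns to a gap in
#' the query; `LOW_CONFIDENCE` when the identity fraction (identical
#' columns over all alignment columns) falls below the configured floor —
#' the anchor is still returned.
#'
#' @param query A sequence string or one-row [read_fasta()] record (its
#'   `id` is carried through).
#' @param reference_subunit A `subunit_record` or registry name; must carry
#'   an M2 fragment and filter offset.
#' @param config See [anchor_config()].
#' @param registry Registry for name resolution.
#' @return An `anchor_result`: list with `query_id`, `reference_subunit`,
#'   `aligned_query_position` (1-based; `NA` if no homologous residue),
#'   `query_residue`, `alignment_score`, `identity_fraction`, `flags`
#'   (character vector, possibly empty).
#' @export
#' @examples
#' anchor_filter_residue("GALTSSAMWFSNVLLNSGIGE", "GluN1")
anchor_filter_residue <- function(query, reference_subunit,
                                  config = anchor_config(),
                                  registry = subunit_registry()) {
  if (is.character(reference_subunit)) {
    reference_subunit <- get_subunit(reference_subunit, registry)
  }
  stopifnot(inherits(reference_subunit, "subunit_record"))
  if (is.na(reference_subunit$m2_fragment) ||
      is.na(reference_subunit$filter_offset)) {
    stop("subunit ", reference_subunit$name, " has no M2 reference ",
         "fragment; it supports ring-charge prediction but not anchoring",
         call. = FALSE)
  }
  qid <- if (is.data.frame(query)) query$id else "query"
  aln <- align_global(query, reference_subunit$m2_fragment, config)
  idn <- sum(!is.na(aln$map$qpos) & !is.na(aln$map$rpos) &
               aln$map$qchar == aln$map$rchar) / nrow(aln$map)
  col <- which(aln$map$rpos == reference_subunit$filter_offset)
  stopifnot(length(col) == 1L)
  qp <- aln$map$qpos[col]
  flags <- character(0)
  if (is.na(qp)) flags <- c(flags, "NO_HOMOLOGOUS_RESIDUE")
  if (idn < config$identity_floor) {
    flags <- c(flags, "LOW_CONFIDENCE")
    warning("anchor identity ", sprintf("%.4f", idn), " for '", qid,
            "' vs ", reference_subunit$name, " is below the floor of ",
            config$identity_floor, call. = FALSE)
  }
  structure(
    list(
      query_id = qid,
      reference_subunit = reference_subunit$name,
      aligned_query_position = qp,
      query_residue = if (is.na(qp)) NA_character_ else aln$map$qchar[col],
      alignment_score = aln$score,
      identity_fraction = idn,
      flags = flags
    ),
    class = "anchor_result"
  )
}

#' @export
print.anchor_result <- function(x, ...) {
  cat(sprintf("<anchor> %s vs %s: ", x$query_id, x$reference_subunit))
  if (is.na(x$aligned_query_position)) {
    cat("no homologous residue\n")
  } else {
    cat(sprintf("residue %s at query position %d\n",
                x$query_residue, x$aligned_query_position))
  }
  cat(sprintf("  score %d, identity %.4f%s\n", x$alignment_score,
              x$identity_fraction,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ";"), "]")
              else ""))
  invisible(x)
}

#' Anchor every record of a FASTA file
#'
#' @param fasta Path to a FASTA file (validated by [read_fasta()]).
#' @inheritParams anchor_filter_residue
#' @return A data.frame, one row per query in input order: `query_id`,
#'   `reference`, `position`, `residue`, `score`, `identity`, `flags`.
#' @export
anchor_fasta <- function(fasta, reference_subunit,
                         config = anchor_config(),
                         registry = subunit_registry()) {
  recs <- read_fasta(fasta)
  rows <- lapply(seq_len(nrow(recs)), function(k) {
    a <- suppressWarnings(
      anchor_filter_residue(recs[k, ], reference_subunit, config, registry)
    )
    data.frame(
      query_id = a$query_id, reference = a$reference_subunit,
      position = a$aligned_query_position,
      residue = ifelse(is.na(a$query_residue), NA_character_,
                       a$query_residue),
      score = a$alignment_score,
      identity = round(a$identity_fraction, 4),
      flags = paste(a$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
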