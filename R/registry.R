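# Registry loading is cached per session; the table ships as plain TSV so
# users can extend it with the same columns via the `path` argument.

.registry_env <- new.env(parent = emptyenv())

.load_registry <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .registry_env$builtin
    if (!is.null(cached)) return(cached)
    reg_path <- system.file("extdata", "subunit_registry.tsv",
                            package = "ringcharge", mustWork = TRUE)
    frag_path <- system.file("extdata", "m2_fragments_synthetic.tsv",
                             package = "ringcharge", mustWork = TRUE)
  } else {
    reg_path <- path
    frag_path <- NA_character_
  }
  reg <- read.delim(reg_path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "family", "filter_residue", "filter_position",
              "accession")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    stop("registry file lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$name)) {
    stop("registry contains duplicate subunit names", call. = FALSE)
  }
  if (!is.na(frag_path)) {
    frag <- read.delim(frag_path, comment.char = "#",
                       stringsAsFactors = FALSE)
    reg <- merge(reg, frag, by = "name", all.x = TRUE, sort = FALSE)
  }
  if (is.null(reg$m2_fragment)) reg$m2_fragment <- NA_character_
  if (is.null(reg$filter_offset)) reg$filter_offset <- NA_integer_
  reg$filter_position <- suppressWarnings(as.integer(reg$filter_position))
  reg$filter_offset <- suppressWarnings(as.integer(reg$filter_offset))
  ok <- is.na(reg$m2_fragment) | is.na(reg$filter_offset) |
    substr(reg$m2_fragment, reg$filter_offset, reg$filter_offset) ==
      reg$filter_residue
  if (!all(ok)) {
    stop("registry fragment/filter mismatch for: ",
         paste(reg$name[!ok], collapse = ", "), call. = FALSE)
  }
  if (is.null(path)) .registry_env$builtin <- reg
  reg
}

#' The subunit registry
#'
#' One record per iGluR subunit covered by the model: GluN1, GluN2A-D,
#' GluN3A/B, GluA1-4 and the Q/R-edited form `GluA2*`. Each record carries
#' the one-letter filter residue at the selectivity-filter position of the
#' M2 re-entrant loop, the residue number within the subunit where the
#' literature prints one (GluN1 598, GluA2 605, GluN2A 614; `NA` otherwise),
#' the UniProtKB accession as provenance metadata, and a synthetic M2
#' stand-in fragment used only by the anchoring machinery (see
#' `inst/extdata/m2_fragments_synthetic.tsv`).
#'
#' @param path Optional path to a user registry in the same TSV format;
#'   defaults to the built-in table.
#' @return A data.frame with columns `name`, `family`, `filter_residue`,
#'   `filter_position`, `accession`, `note`, `filter_offset`, `m2_fragment`.
#' @export
#' @examples
#' subunit_registry()[, c("name", "family", "filter_residue")]
subunit_registry <- function(path = NULL) .load_registry(path)

#' Look up one subunit record
#'
#' @param name Subunit name, matched case-insensitively against the registry.
#' @param registry Registry table, defaulting to [subunit_registry()].
#' @return A `subunit_record`: a one-row list with the registry fields.
#' @export
#' @examples
#' get_subunit("GluN1")
#' get_subunit("glua2*")
get_subunit <- function(name, registry = subunit_registry()) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- match(toupper(name), toupper(registry$name))
  if (is.na(hit)) {
    stop("unknown subunit '", name, "'; registry knows: ",
         paste(registry$name, collapse = ", "), call. = FALSE)
  }
  rec <- as.list(registry[hit, , drop = FALSE])
  rec <- lapply(rec, unname)
  structure(rec, class = "subunit_record")
}

#' @export
print.subunit_record <- function(x, ...) {
  pos <- if (is.na(x$filter_position)) "UNKNOWN" else x$filter_position
  cat(sprintf("<subunit> %s (family %s): filter residue %s at position %s\n",
              x$name, x$family, x$filter_residue, pos))
  invisible(x)
}

#' Ring-charge contribution of one filter residue
#'
#' Polar uncharged hydrophilic side chains (N, Q, S, T) present a partial
#' negative charge to the pore; the model treats each as a full elementary
#' charge, contribution -1. Every other standard residue contributes 0 —
#' including the positively charged R and K, whose side chains point away
#' from the pore axis in this scheme (forced by the printed facts that two
#' R-bearing subunits take the ring from -4 to -2 and four take it to 0).
#' Acidic D and E never occur at a filter position in the reference set;
#' they are mapped to -1 (full negative charge, consistent with partial
#' charges being promoted to full) and flagged with a warning as an
#' extrapolation.
#'
#' @param residue One-letter amino-acid code(s); vectorised.
#' @return Integer vector of contributions in `{-1, 0}`.
#' @export
#' @examples
#' residue_contribution(c("N", "Q", "G", "R"))
residue_contribution <- function(residue) {
  stopifnot(is.character(residue), all(nchar(residue) == 1L))
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- toupper(residue)
  bad <- setdiff(unique(res), std)
  if (length(bad)) {
    stop("not a standard one-letter amino-acid code: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(res %in% c("D", "E"))) {
    warning("acidic residue (D/E) at a filter position: contribution -1 is ",
            "an extrapolation beyond the reference residue set",
            call. = FALSE)
  }
  ifelse(res %in% c("N", "Q", "S", "T", "D", "E"), -1L, 0L)
}

#' Assemble a receptor from subunit records
#'
#' @param subunits A list of `subunit_record`s or character vector of
#'   registry names, in display order. Order is preserved for display but
#'   ring charge is a permutation-invariant sum.
#' @param hypothetical Synaptic AMPA/NMDA receptors are tetramers; pass
#'   `TRUE` to allow hypothetical n-mers (n >= 3), e.g. the pentamer and
#'   hexamer thought experiments.
#' @param registry Registry used to resolve character names.
#' @return A `receptor_assembly`: list with `subunits` (list of records),
#'   `n`, `hypothetical` and `ring` (integer ring charge).
#' @export
#' @examples
#' receptor_assembly(c("GluN1", "GluN2A", "GluN1", "GluN2A"))
receptor_assembly <- function(subunits, hypothetical = FALSE,
                              registry = subunit_registry()) {
  if (is.character(subunits)) {
    subunits <- lapply(subunits, get_subunit, registry = registry)
  }
  stopifnot(is.list(subunits),
            all(vapply(subunits, inherits, TRUE, "subunit_record")))
  n <- length(subunits)
  if (!hypothetical && n != 4L) {
    stop("stoichiometry error: synaptic AMPA/NMDA receptors are tetramers ",
         "(got ", n, " subunits); pass hypothetical = TRUE for other n-mers",
         call. = FALSE)
  }
  if (hypothetical && n < 3L) {
    stop("stoichiometry error: assemblies need at least 3 subunits",
         call. = FALSE)
  }
  fams <- vapply(subunits, `[[`, "", "family")
  if (any(grepl("^GluN", fams)) && any(fams == "GluA")) {
    warning("mixed NMDA (GluN) and AMPA (GluA) subunits in one assembly: ",
            "not a native receptor, evaluating the residue ring anyway",
            call. = FALSE)
  } else if (any(grepl("^GluN", fams)) && !any(fams == "GluN1")) {
    warning("NMDA-family assembly without the obligatory GluN1 subunit: ",
            "not a native receptor, evaluating the residue ring anyway",
            call. = FALSE)
  }
  residues <- vapply(subunits, `[[`, "", "filter_residue")
  unresolved <- vapply(subunits, function(s) {
    is.na(s$filter_residue) || !nzchar(s$filter_residue)
  }, TRUE)
  if (any(unresolved)) {
    stop("subunits with unresolved filter residues: ",
         paste(vapply(subunits[unresolved], `[[`, "", "name"),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      subunits = subunits, n = n, hypothetical = hypothetical,
      ring = sum(residue_contribution(residues))
    ),
    class = "receptor_assembly"
  )
}

#' @export
print.receptor_assembly <- function(x, ...) {
  cat(sprintf("<receptor assembly> %s\n",
              paste(vapply(x$subunits, `[[`, "", "name"), collapse = "/")))
  cat(sprintf("  n = %d%s, filter ring %s, ring charge r_q = %d\n",
              x$n, if (x$hypothetical) " (hypothetical n-mer)" else "",
              paste(vapply(x$subunits, `[[`, "", "filter_residue"),
                    collapse = "-"),
              x$ring))
  invisible(x)
}

#' Total selectivity-filter ring charge of an assembly
#'
#' The signed integer sum of per-subunit filter-residue contributions;
#' always `<= 0` since no residue contributes positively.
#'
#' @param assembly A [receptor_assembly()], or anything
#'   [parse_composition()] accepts.
#' @inheritParams receptor_assembly
#' @return Integer ring charge.
#' @export
#' @examples
#' ring_charge("GluN1/GluN2A/GluN1/GluN2A")   # -4
#' ring_charge("GluN1/GluN3A/GluN1/GluN3A")   # -2
#' ring_charge("GluA2*/GluA2*/GluA2*/GluA2*") # 0 (R-form homomer)
ring_charge <- function(assembly, hypothetical = FALSE,
                        registry = subunit_registry()) {
  if (!inherits(assembly, "receptor_assembly")) {
    assembly <- parse_composition(assembly, hypothetical = hypothetical,
                                  registry = registry)
  }
  assembly$ring
}

#' Parse a receptor composition string
#'
#' Compositions are written as slash-delimited subunit names
#' (`"GluN1/GluN2A/GluN1/GluN2A"`). Hyphens also delimit when no slash is
#' present, supporting the compact `"GluN1-2A-1-2A"` style, where bare
#' tokens such as `"2A"` or `"1"` are resolved against the family prefix
#' (`GluN`/`GluA`) of the most recent fully named subunit. Matching is
#' case-insensitive; `"GluA2*"` names the edited (Q->R) GluA2 form.
#'
#' @param text Composition string (or an already-built assembly, returned
#'   unchanged; or a character vector of names, one per subunit).
#' @inheritParams receptor_assembly
#' @return A [receptor_assembly()].
#' @export
#' @examples
#' parse_composition("GluN1-2B-3A-2B")     # t-NMDAR, r_q = -3
#' parse_composition("GluA1/GluA2*/GluA1/GluA2*")
parse_composition <- function(text, hypothetical = FALSE,
                              registry = subunit_registry()) {
  if (inherits(text, "receptor_assembly")) return(text)
  stopifnot(is.character(text))
  tokens <- if (length(text) > 1L) text else {
    t1 <- trimws(strsplit(text, "/", fixed = TRUE)[[1]])
    if (length(t1) > 1L) t1 else trimws(strsplit(text, "-", fixed = TRUE)[[1]])
  }
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty composition string", call. = FALSE)
  family_prefix <- NA_character_
  names_resolved <- character(length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    hit <- match(toupper(tok), toupper(registry$name))
    if (is.na(hit) && !is.na(family_prefix)) {
      hit <- match(toupper(paste0(family_prefix, tok)),
                   toupper(registry$name))
    }
    if (is.na(hit)) {
      stop("unknown subunit token '", tok, "' in composition",
           if (is.na(family_prefix)) "" else
             paste0(" (also tried ", family_prefix, tok, ")"),
           call. = FALSE)
    }
    names_resolved[k] <- registry$name[hit]
    family_prefix <- sub("^(Glu[NA]).*$", "\\1", registry$name[hit])
  }
  receptor_assembly(names_resolved, hypothetical = hypothetical,
                    registry = registry)
}

#' In-silico point mutation of a subunit filter region
#'
#' Creates a mutant record carrying the substituted residue, named with the
#' standard mutation label (e.g. `GluN1-N598Q`). The position is given in
#' the subunit's own (paper) numbering and must be resolvable: either it is
#' the record's known `filter_position`, or it falls inside the record's M2
#' fragment (whose coordinates follow from `filter_position` and
#' `filter_offset`). Records whose `filter_position` is unknown cannot be
#' mutated.
#'
#' @param subunit A `subunit_record` or registry name.
#' @param position 1-based residue number in subunit coordinates.
#' @param new_residue One-letter code of the replacement.
#' @param registry Registry used to resolve a character `subunit`.
#' @return A new `subunit_record`; the original is untouched.
#' @export
#' @examples
#' mutate_subunit("GluN1", 598, "Q")   # N598Q: contribution still -1
#' mutate_subunit("GluA2", 605, "R")   # Q605R: the editing-site switch
mutate_subunit <- function(subunit, position, new_residue,
                           registry = subunit_registry()) {
  if (is.character(subunit)) subunit <- get_subunit(subunit, registry)
  stopifnot(inherits(subunit, "subunit_record"))
  pos <- .check_integerish(position, "position")
  stopifnot(is.character(new_residue), nchar(new_residue) == 1L)
  new_residue <- toupper(new_residue)
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!new_residue %in% std) {
    stop("replacement '", new_residue,
         "' is not a standard one-letter amino-acid code", call. = FALSE)
  }
  if (is.na(subunit$filter_position)) {
    stop("subunit ", subunit$name, " has no known filter position; ",
         "cannot resolve subunit coordinates for mutation", call. = FALSE)
  }
  out <- subunit
  if (pos == subunit$filter_position) {
    old <- subunit$filter_residue
    out$filter_residue <- new_residue
    if (!is.na(subunit$m2_fragment) && !is.na(subunit$filter_offset)) {
      substr(out$m2_fragment, subunit$filter_offset,
             subunit$filter_offset) <- new_residue
    }
  } else {
    if (is.na(subunit$m2_fragment) || is.na(subunit$filter_offset)) {
      stop("position ", pos, " is not the filter position of ",
           subunit$name, " and the record has no M2 fragment to resolve it",
           call. = FALSE)
    }
    frag_start <- subunit$filter_position - subunit$filter_offset + 1L
    idx <- pos - frag_start + 1L
    if (idx < 1L || idx > nchar(subunit$m2_fragment)) {
      stop("position ", pos, " lies outside the known coordinates of ",
           subunit$name, " (fragment spans ", frag_start, "-",
           frag_start + nchar(subunit$m2_fragment) - 1L, ")", call. = FALSE)
    }
    old <- substr(subunit$m2_fragment, idx, idx)
    substr(out$m2_fragment, idx, idx) <- new_residue
  }
  if (old == new_residue) {
    stop("position ", pos, " of ", subunit$name, " is already ", old,
         call. = FALSE)
  }
  out$name <- sprintf("%s-%s%d%s", subunit$name, old, pos, new_residue)
  out$note <- sprintf("in-silico mutant of %s (%s%d%s)",
                      subunit$name, old, pos, new_residue)
  out
}

#' Validate a mutation label against the stored reference residue
#'
#' Convenience wrapper accepting labels like `"N598Q"`; errors if the stored
#' residue at that position differs from the label's reference residue.
#'
#' @inheritParams mutate_subunit
#' @param label Mutation label `"<ref><position><new>"`.
#' @return A mutant `subunit_record`.
#' @export
#' @examples
#' apply_mutation("GluA2", "Q605R")
apply_mutation <- function(subunit, label, registry = subunit_registry()) {
  if (is.character(subunit)) subunit <- get_subunit(subunit, registry)
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m) != 4L) {
    stop("malformed mutation label '", label, "'; expected e.g. N598Q",
         call. = FALSE)
  }
  ref <- toupper(m[2]); pos <- as.integer(m[3]); new <- toupper(m[4])
  stored <- .residue_at(subunit, pos)
  if (!identical(stored, ref)) {
    stop("mutation ", label, ": expected ", ref, " at position ", pos,
         " of ", subunit$name, " but found ",
         if (is.na(stored)) "no resolvable residue" else stored,
         call. = FALSE)
  }
  mutate_subunit(subunit, pos, new, registry)
}

.residue_at <- function(subunit, pos) {
  if (is.na(subunit$filter_position)) return(NA_character_)
  if (pos == subunit$filter_position) return(subunit$filter_residue)
  if (is.na(subunit$m2_fragment) || is.na(subunit$filter_offset)) {
    return(NA_character_)
  }
  frag_start <- subunit$filter_position - subunit$filter_offset + 1L
  idx <- pos - frag_start + 1L
  if (idx < 1L || idx > nchar(subunit$m2_fragment)) return(NA_character_)
  substr(subunit$m2_fragment, idx, idx)
}

#' Export an assembly as a one-row table
#'
#' @param assembly A [receptor_assembly()].
#' @return A data.frame with `composition`, `n`, `residue_ring`, `r_q`.
#' @export
assembly_table <- function(assembly) {
  stopifnot(inherits(assembly, "receptor_assembly"))
  data.frame(
    composition = paste(vapply(assembly$subunits, `[[`, "", "name"),
                        collapse = "/"),
    n = assembly$n,
    residue_ring = paste(vapply(assembly$subunits, `[[`, "",
                                "filter_residue"), collapse = ""),
    r_q = assembly$ring,
    stringsAsFactors = FALSE
  )
}
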