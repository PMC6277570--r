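#' Read an SDF (V2000) file into a molecule table
#'
#' Parses each `$$$$`-delimited record with ChemmineR and computes, per
#' molecule, the element set, the number of connected fragments in the
#' bond graph, and the standard InChI (which includes the
#' stereochemistry layer) used as the canonical identifier for
#' duplicate detection. Records that cannot be parsed, or for which no
#' InChI can be derived, are skipped and counted — bulk SDF exports
#' routinely contain a few broken entries and a single bad record should
#' not abort a curation run.
#'
#' @param path Path to an SDF file.
#' @param source_set Optional set label (`"positive"`/`"negative"`)
#'   stamped on every record.
#' @return A `molecule_set` tibble with columns `record_id` (ordinal in
#'   the file), `source_set`, `canonical_id` (InChI), `n_atoms`,
#'   `elements` (list of element symbols), `n_fragments`, and `lines`
#'   (the raw record text, kept so cleaned sets can be re-written
#'   losslessly). Attribute `parse_failures` counts skipped records.
#' @export
read_sdf <- function(path, source_set = NA_character_) {
  if (!file.exists(path)) abort(sprintf("SDF file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$\\s*$", raw)
  if (length(ends) == 0L) {
    ends <- length(raw)
  } else if (max(ends) < length(raw) &&
             any(nzchar(trimws(raw[(max(ends) + 1L):length(raw)])))) {
    # final record not terminated by $$$$
    ends <- c(ends, length(raw))
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- purrr::map2(starts, ends, function(s, e) raw[s:e])
  # drop a trailing all-blank pseudo-record
  recs <- purrr::keep(recs, function(r) any(nzchar(trimws(r))))
  if (length(recs) == 0L) abort(sprintf("no SDF records in %s", path))

  parse_one <- function(rec, ordinal) {
    if (!any(grepl("^\\$\\$\\$\\$", rec))) rec <- c(rec, "$$$$")
    # invalid records are counted as parse failures, so ChemmineR's
    # advisory warnings about them are noise here
    sdfset <- tryCatch(suppressWarnings({
      cls <- methods::getClass("SDFstr", where = asNamespace("ChemmineR"))
      methods::as(methods::new(cls, a = list(rec)), "SDFset")
    }), error = function(e) NULL)
    if (is.null(sdfset) ||
        !isTRUE(suppressWarnings(ChemmineR::validSDF(sdfset))[1L])) {
      return(NULL)
    }
    sdf <- sdfset[[1L]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0L) return(NULL)
    bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
    g <- igraph::make_empty_graph(n = nrow(ab), directed = FALSE)
    if (!is.null(bb) && nrow(bb) > 0L) {
      g <- igraph::add_edges(g, rbind(as.integer(bb[, 1L]),
                                      as.integer(bb[, 2L])))
    }
    n_frag <- igraph::components(g)$no
    inchi <- tryCatch(
      trimws(ChemmineOB::convertFormat(
        "SDF", "INCHI", paste(c(rec, ""), collapse = "\n"))),
      error = function(e) ""
    )
    if (!nzchar(inchi) || !startsWith(inchi, "InChI=")) return(NULL)
    # element set from the InChI formula layer, so implicit hydrogens
    # are counted even though the connection table omits them
    elements <- .inchi_elements(inchi)
    tibble(
      record_id = ordinal, source_set = source_set,
      canonical_id = inchi, n_atoms = nrow(ab),
      elements = list(elements), n_fragments = n_frag,
      lines = list(rec)
    )
  }
  parsed <- purrr::imap(recs, parse_one)
  failures <- sum(vapply(parsed, is.null, logical(1)))
  out <- dplyr::bind_rows(parsed)
  if (nrow(out) == 0L) {
    abort(sprintf("no parseable SDF records in %s (%d failures)",
                  path, failures))
  }
  structure(out, class = c("molecule_set", class(tibble())),
            parse_failures = failures, n_raw = length(recs),
            source_path = path)
}

# Element symbols from an InChI's formula layer (components split on
# ".", leading stoichiometric multipliers ignored).
.inchi_elements <- function(inchi) {
  formula <- strsplit(inchi, "/", fixed = TRUE)[[1L]][2L]
  if (is.na(formula)) return(character())
  comps <- strsplit(formula, ".", fixed = TRUE)[[1L]]
  syms <- unlist(regmatches(comps, gregexpr("[A-Z][a-z]?", comps)))
  unique(syms)
}

.default_elements <- c("C", "H", "O", "N", "P", "S", "Cl", "Br", "I", "Si")

#' Remove hydrocarbons and molecules with non-whitelisted elements
#'
#' Two removal rules applied in one pass: molecules whose heavy atoms
#' are carbon only (hydrocarbons; hydrogens are ignored) are removed,
#' and molecules containing any element outside the whitelist
#' C H O N P S Cl Br I Si are removed. Row order is preserved.
#'
#' @param mols A molecule table from [read_sdf()].
#' @param allowed Element whitelist.
#' @return A list with `kept` and `removed`; `removed` gains a `reason`
#'   column (`"hydrocarbon"` or `"element"`).
#' @export
element_filter <- function(mols, allowed = .default_elements) {
  heavy <- purrr::map(mols$elements, setdiff, y = "H")
  is_hydrocarbon <- purrr::map_lgl(heavy, function(e) {
    length(e) > 0L && all(e == "C")
  })
  has_foreign <- purrr::map_lgl(mols$elements, function(e) {
    any(!e %in% allowed)
  })
  removed <- mols[is_hydrocarbon | has_foreign, , drop = FALSE]
  removed$reason <- ifelse(is_hydrocarbon[is_hydrocarbon | has_foreign],
                           "hydrocarbon", "element")
  list(kept = mols[!(is_hydrocarbon | has_foreign), , drop = FALSE],
       removed = removed)
}

#' Remove multi-fragment records (salts, solvates, mixtures)
#'
#' A record whose bond graph has more than one connected component
#' represents more than one molecule and is removed whole — no fragment
#' keeping.
#'
#' @param mols A molecule table.
#' @return A list with `kept` and `removed`.
#' @export
remove_mixtures <- function(mols) {
  mixture <- mols$n_fragments > 1L
  list(kept = mols[!mixture, , drop = FALSE],
       removed = mols[mixture, , drop = FALSE])
}

#' Deduplicate within and across the two class sets
#'
#' Two molecules with the same InChI (stereochemistry included) are
#' duplicates. Within each set only the first occurrence (input order)
#' is kept; a molecule present in both sets is removed from the
#' negative set only.
#'
#' @param positive,negative Molecule tables for the two classes.
#' @return A list with `positive`, `negative`, and a `counts` list:
#'   `removed_within_positive`, `removed_within_negative`,
#'   `removed_cross_set`.
#' @export
deduplicate <- function(positive, negative) {
  dup_pos <- duplicated(positive$canonical_id)
  dup_neg <- duplicated(negative$canonical_id)
  pos <- positive[!dup_pos, , drop = FALSE]
  neg <- negative[!dup_neg, , drop = FALSE]
  cross <- neg$canonical_id %in% pos$canonical_id
  neg_out <- neg[!cross, , drop = FALSE]
  if (nrow(pos) == 0L) abort("positive set is empty after deduplication")
  if (nrow(neg_out) == 0L) abort("negative set is empty after deduplication")
  list(
    positive = pos, negative = neg_out,
    counts = list(
      removed_within_positive = sum(dup_pos),
      removed_within_negative = sum(dup_neg),
      removed_cross_set = sum(cross)
    )
  )
}

#' Run the full cleaning pipeline on a positive and a negative set
#'
#' Applies, in fixed order: the optional structure normalizer hook, the
#' element filter (hydrocarbons, element whitelist), mixture removal,
#' and InChI deduplication (within sets, then across, dropping shared
#' structures from the negative set). The rule order is a convention of
#' this implementation; the full pipeline is idempotent, so cleaning an
#' already-clean set removes nothing.
#'
#' The `normalizer` slot is where a structure standardizer
#' (neutralize / tautomerize / aromatize) would plug in; the default is
#' the identity, a documented fidelity gap relative to workflows that
#' standardize with commercial tools before deduplication.
#'
#' @param positive,negative Molecule tables from [read_sdf()].
#' @param normalizer Optional function `molecule_set -> molecule_set`
#'   applied before any filtering.
#' @return A list with cleaned `positive` and `negative` tables and a
#'   `report` tibble of per-set counts whose columns always reconcile:
#'   `input_count = output_count + removals + parse_failures`.
#' @export
clean_molecules <- function(positive, negative, normalizer = NULL) {
  if (!is.null(normalizer)) {
    positive <- normalizer(positive)
    negative <- normalizer(negative)
  }
  stage <- function(mols) {
    ef <- element_filter(mols)
    mx <- remove_mixtures(ef$kept)
    list(
      kept = mx$kept,
      removed_hydrocarbon = sum(ef$removed$reason == "hydrocarbon"),
      removed_element = sum(ef$removed$reason == "element"),
      removed_mixture = nrow(mx$removed)
    )
  }
  sp <- stage(positive)
  sn <- stage(negative)
  dd <- deduplicate(sp$kept, sn$kept)
  report <- tibble(
    set = c("positive", "negative"),
    input_count = c(attr(positive, "n_raw") %||% nrow(positive),
                    attr(negative, "n_raw") %||% nrow(negative)),
    parse_failures = c(attr(positive, "parse_failures") %||% 0L,
                       attr(negative, "parse_failures") %||% 0L),
    removed_hydrocarbon = c(sp$removed_hydrocarbon, sn$removed_hydrocarbon),
    removed_element = c(sp$removed_element, sn$removed_element),
    removed_mixture = c(sp$removed_mixture, sn$removed_mixture),
    removed_duplicate_within = c(dd$counts$removed_within_positive,
                                 dd$counts$removed_within_negative),
    removed_cross_set = c(0L, dd$counts$removed_cross_set),
    output_count = c(nrow(dd$positive), nrow(dd$negative))
  )
  list(positive = dd$positive, negative = dd$negative, report = report)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a molecule table back to SDF
#'
#' Emits the raw record text kept by [read_sdf()], so the output is a
#' byte-faithful subset of the input file.
#'
#' @param mols A molecule table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  writeLines(unlist(mols$lines), path)
  invisible(path)
}

#' Write a cleaning report as JSON
#'
#' @param report The `report` tibble from [clean_molecules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
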