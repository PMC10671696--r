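#' Parse an HGVS-style cDNA variant description
#'
#' Recognises the LDLR cDNA notations used in variant tables: substitutions
#' (`c.268 G>A`), duplications (`c.837 dupC`), deletions (`c.2001_2002 del`)
#' and intronic offsets (`c.1060+2 T>C`, `c.1706-1 G>C`). Whitespace between
#' tokens is tolerated. Coordinates are 1-based on the reference transcript.
#'
#' @param text A single HGVS-style `c.` string.
#' @return A list of class `fh_cdna` with fields `kind` (`"substitution"`,
#'   `"duplication"`, `"deletion"`), `position`, `end` (deletions only),
#'   `offset` (signed intronic offset, 0 if exonic), `intronic` (flag),
#'   `ref`/`alt` (substitutions), `seq` (duplications), and `text` (the
#'   canonical rendering, see [format_cdna()]).
#' @export
#' @examples
#' parse_cdna("c.1241 T>G")
#' parse_cdna("c.1060+2 T>C")$offset   # 2
parse_cdna <- function(text) {
  if (length(text) != 1 || !is.character(text) || !nzchar(trimws(text))) {
    stop("parse_cdna() needs a single non-empty string", call. = FALSE)
  }
  s <- gsub("\\s+", "", text)
  pos_re <- "(\\d+)([+-]\\d+)?"

  m <- regmatches(s, regexec(paste0("^c\\.", pos_re, "([ACGT])>([ACGT])$"), s))[[1]]
  if (length(m) > 0) {
    return(new_cdna("substitution", text,
                    position = as.integer(m[2]), offset = parse_offset(m[3]),
                    ref = m[4], alt = m[5]))
  }
  m <- regmatches(s, regexec(paste0("^c\\.", pos_re, "(?:_", pos_re, ")?dup([ACGT]*)$"), s))[[1]]
  if (length(m) > 0) {
    return(new_cdna("duplication", text,
                    position = as.integer(m[2]), offset = parse_offset(m[3]),
                    end = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
                    seq = m[6]))
  }
  m <- regmatches(s, regexec(paste0("^c\\.", pos_re, "(?:_", pos_re, ")?del([ACGT]*)$"), s))[[1]]
  if (length(m) > 0) {
    return(new_cdna("deletion", text,
                    position = as.integer(m[2]), offset = parse_offset(m[3]),
                    end = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
                    seq = m[6]))
  }
  stop("cannot parse cDNA notation: '", text, "'", call. = FALSE)
}

parse_offset <- function(x) {
  if (is.na(x) || !nzchar(x)) 0L else as.integer(x)
}

new_cdna <- function(kind, original, position, offset = 0L, end = NA_integer_,
                     ref = NA_character_, alt = NA_character_,
                     seq = NA_character_) {
  out <- list(kind = kind, position = position, end = end,
              offset = offset, intronic = offset != 0L,
              ref = ref, alt = alt, seq = seq)
  out$text <- format_cdna_fields(out)
  structure(out, class = "fh_cdna")
}

format_cdna_fields <- function(x) {
  pos <- paste0(x$position,
                if (x$offset != 0L) sprintf("%+d", x$offset) else "")
  range <- if (!is.na(x$end)) paste0(pos, "_", x$end) else pos
  switch(x$kind,
    substitution = paste0("c.", pos, x$ref, ">", x$alt),
    duplication = paste0("c.", range, "dup",
                         if (!is.na(x$seq) && nzchar(x$seq)) x$seq else ""),
    deletion = paste0("c.", range, "del",
                      if (!is.na(x$seq) && nzchar(x$seq)) x$seq else "")
  )
}

#' Canonical rendering of a parsed cDNA change
#' @param x An `fh_cdna` from [parse_cdna()].
#' @return The canonical HGVS-style string (no internal whitespace).
#' @export
format_cdna <- function(x) {
  stopifnot(inherits(x, "fh_cdna"))
  x$text
}

#' @export
print.fh_cdna <- function(x, ...) {
  cat(x$text, " (", x$kind,
      if (x$intronic) paste0(", intronic offset ", sprintf("%+d", x$offset)),
      ")\n", sep = "")
  invisible(x)
}

#' Classify the molecular consequence of a variant
#'
#' Applies, in order: a protein change containing `Ter`/`*` without a
#' frameshift marker is nonsense; `fs` is frameshift; an intronic change
#' within the configured near-splice window (default +/-5; canonical sites
#' are +/-1 or 2) or an annotation describing a new/disrupted splice site is
#' splice -- or `synonymous_splice` when the protein change is synonymous
#' (`=`); any remaining amino-acid substitution is missense.
#'
#' @param change An `fh_cdna` from [parse_cdna()].
#' @param protein_change Protein-level annotation string (may be `NA`); free
#'   text such as `"Splice donor variant"` is also examined for splice cues.
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @return One of `"missense"`, `"nonsense"`, `"frameshift"`, `"splice"`,
#'   `"synonymous_splice"`.
#' @export
#' @examples
#' classify_consequence(parse_cdna("c.1448 G>A"), "p.(Trp483Ter)")  # nonsense
classify_consequence <- function(change, protein_change = NA_character_,
                                 config = NULL) {
  stopifnot(inherits(change, "fh_cdna"))
  cfg <- as_fh_config(config)
  window <- cfg$variant_rules$near_splice_window %||% 5
  prot <- if (is.na(protein_change)) "" else protein_change
  has_fs <- grepl("fs", prot)
  has_ter <- grepl("Ter|\\*", prot)
  splice_annotated <- grepl("splice", prot, ignore.case = TRUE)
  synonymous <- grepl("=", prot, fixed = TRUE)

  if (has_fs) {
    return("frameshift")
  }
  if (has_ter) {
    return("nonsense")
  }
  if ((change$intronic && abs(change$offset) <= window) || splice_annotated) {
    return(if (synonymous) "synonymous_splice" else "splice")
  }
  if (change$intronic) {
    return("splice")  # deeper intronic but reported: treat as splice-affecting
  }
  "missense"
}

#' Expected LDLR receptor class of a consequence
#'
#' Truncating or splice-disrupting changes (nonsense, frameshift, splice,
#' synonymous-with-new-splice-site) are expected receptor-negative; missense
#' changes, which typically retain residual receptor activity, are expected
#' receptor-defective. The map is configurable (`variant_rules$receptor_class`).
#'
#' @param consequence One of the values returned by [classify_consequence()].
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @return `"negative"` or `"defective"` (vectorised).
#' @export
expected_receptor_class <- function(consequence, config = NULL) {
  cfg <- as_fh_config(config)
  map <- cfg$variant_rules$receptor_class
  out <- vapply(consequence, function(cq) {
    cls <- map[[cq]]
    if (is.null(cls)) {
      stop("no receptor class configured for consequence '", cq, "'",
           call. = FALSE)
    }
    cls
  }, character(1))
  unname(out)
}

#' Read a variant table
#'
#' Reads a TSV with one row per distinct variant: columns `cdna`,
#' `protein_change`, `localization` (e.g. `"exon 9"`, `"intron 7"`),
#' `n_probands`, `n_cascade`, `clinical_significance` (annotation only,
#' carried not computed) and `novel`. Each `cdna` entry is parsed, and
#' consequence and expected receptor class are derived.
#'
#' @param path Path to the TSV file.
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @return A tibble with the file's columns plus `kind`, `consequence` and
#'   `receptor_class`.
#' @export
read_variant_table <- function(path, config = NULL) {
  cfg <- as_fh_config(config)
  if (!file.exists(path)) {
    stop("variant table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    stop("variant table is empty: ", path, call. = FALSE)
  }
  required <- c("cdna", "protein_change", "localization", "n_probands",
                "n_cascade", "clinical_significance", "novel")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("variant table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$n_probands < 0 | df$n_cascade < 0)) {
    stop("variant counts must be non-negative", call. = FALSE)
  }
  parsed <- lapply(df$cdna, parse_cdna)
  df$kind <- vapply(parsed, `[[`, character(1), "kind")
  df$consequence <- vapply(seq_len(nrow(df)), function(i) {
    classify_consequence(parsed[[i]], df$protein_change[i], cfg)
  }, character(1))
  df$receptor_class <- expected_receptor_class(df$consequence, cfg)
  df$novel <- as.logical(df$novel)
  tibble::as_tibble(df)
}

#' The LDLR variant table shipped with the package
#'
#' Convenience loader for the packaged 22-row LDLR variant spectrum fixture
#' (HGVS cDNA notation, protein change, localization, per-proband and
#' cascade counts, clinical-significance annotation, novelty flag).
#'
#' @inheritParams read_variant_table
#' @return As [read_variant_table()].
#' @export
fh_ldlr_variants <- function(config = NULL) {
  read_variant_table(
    system.file("extdata", "ldlr_variants.tsv", package = "fhdx"),
    config
  )
}

#' Variant spectrum summary
#'
#' Tallies a variant table into the shape of a published spectrum summary:
#' counts by consequence and expected receptor class, variant-detection
#' percentages by cohort stratum, and the expansion of the locally known
#' spectrum contributed by newly reported variants. Percentages are rendered
#' half-up to one decimal.
#'
#' The expansion is `n_new / (prior_total - n_new)` when `prior_total`
#' already includes the new variants (i.e. new over previously known).
#'
#' @param variants A variant tibble from [read_variant_table()].
#' @param n_probands_positive,n_probands_tested Cases with a variant and
#'   probands tested, overall; the detection percentage is their ratio.
#' @param strata Optional named list of `c(positive, tested)` pairs for
#'   additional strata (e.g. `list(adult = c(16, 19), pediatric = c(6, 12))`).
#' @param n_new Number of variants newly reported locally (default: count of
#'   `novel` variants in the table, which only reflects variants never
#'   reported anywhere).
#' @param prior_total Total number of distinct variants reported locally,
#'   including the new ones (`NA` to skip the expansion figure).
#' @return A list of class `fh_spectrum` with the tallies, percentages and
#'   a `notes` character vector flagging any internal count inconsistencies
#'   (these are reported, never silently resolved).
#' @export
spectrum_summary <- function(variants, n_probands_positive = NULL,
                             n_probands_tested = NULL, strata = list(),
                             n_new = NULL, prior_total = NA) {
  by_consequence <- table(variants$consequence)
  by_class <- table(variants$receptor_class)
  n_unique <- nrow(variants)
  n_novel <- sum(variants$novel)
  n_observations <- sum(variants$n_probands)
  if (is.null(n_new)) {
    n_new <- n_novel
  }

  pct_positive <- if (!is.null(n_probands_positive) && !is.null(n_probands_tested)) {
    percent_half_up(n_probands_positive / n_probands_tested)
  } else {
    NA_real_
  }
  strata_pct <- vapply(strata, function(x) percent_half_up(x[1] / x[2]),
                       numeric(1))
  expansion <- if (!is.na(prior_total)) {
    if (prior_total <= n_new) {
      stop("prior_total must exceed n_new (it includes the new variants)",
           call. = FALSE)
    }
    percent_half_up(n_new / (prior_total - n_new))
  } else {
    NA_real_
  }

  notes <- character()
  if (!is.null(n_probands_positive) && n_unique != n_probands_positive &&
      !is.null(n_probands_tested)) {
    notes <- c(notes, sprintf(
      "table lists %d distinct variants across %d probands with a variant; counts need not agree",
      n_unique, n_probands_positive))
  }
  structure(list(
    n_unique_variants = n_unique,
    n_novel = n_novel,
    n_proband_observations = n_observations,
    by_consequence = by_consequence,
    by_receptor_class = by_class,
    percent_probands_positive = pct_positive,
    strata_percent_positive = strata_pct,
    n_new_local = n_new,
    prior_total = prior_total,
    percent_expansion = expansion,
    notes = notes
  ), class = "fh_spectrum")
}

#' @export
print.fh_spectrum <- function(x, ...) {
  cat("LDLR variant spectrum summary\n")
  cat("  distinct variants:", x$n_unique_variants,
      sprintf("(novel: %d)\n", x$n_novel))
  cat("  proband observations:", x$n_proband_observations, "\n")
  cat("  by receptor class:",
      paste(names(x$by_receptor_class), x$by_receptor_class,
            sep = "=", collapse = ", "), "\n")
  cat("  by consequence:",
      paste(names(x$by_consequence), x$by_consequence,
            sep = "=", collapse = ", "), "\n")
  if (!is.na(x$percent_probands_positive)) {
    cat("  probands with a variant:", x$percent_probands_positive, "%\n")
  }
  for (nm in names(x$strata_percent_positive)) {
    cat("   ", nm, ":", x$strata_percent_positive[[nm]], "%\n")
  }
  if (!is.na(x$percent_expansion)) {
    cat(sprintf("  local spectrum expansion: %s%% (%d new of %d total)\n",
                x$percent_expansion, x$n_new_local, x$prior_total))
  }
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}
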