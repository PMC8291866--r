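#' gcmeta: meta-analysis of case-control genotype counts
#'
#' Study-level genotype counts in, pooled genetic-model odds ratios out.
#' The workflow is: read a study table ([read_studies()] or the packaged
#' [cdkn2b_studies()] fixture), screen control genotypes for
#' Hardy-Weinberg equilibrium ([hwe_test()]), derive per-study 2x2 tables
#' and odds ratios for the five genetic models ([effect_estimates()]),
#' pool them under the heterogeneity-driven fixed/random rule
#' ([pool_auto()], [stratify()]), and probe robustness with
#' [leave_one_out()] and [begg_test()].  [simulate_set()] generates
#' synthetic study sets with the same structure for calibration.
#'
#' @docType package
#' @name gcmeta
#' @keywords internal
"_PACKAGE"

# Required columns of the study CSV schema, in canonical order.
STUDY_COLUMNS <- c(
  "study_id", "author", "year", "origin", "variant", "phenotype",
  "ethnicity", "control_source",
  "case_hom_effect", "case_het", "case_hom_other",
  "ctrl_hom_effect", "ctrl_het", "ctrl_hom_other",
  "method"
)

COUNT_COLUMNS <- c(
  "case_hom_effect", "case_het", "case_hom_other",
  "ctrl_hom_effect", "ctrl_het", "ctrl_hom_other"
)

#' Effect allele of a variant
#'
#' The effect allele is the one whose dose defines "exposure" in every
#' genetic-model contrast: C for rs1333049 (G/C) and G for rs4977574
#' (A/G).  Unknown variants (e.g. simulated ones) return `NA`.
#'
#' @param variant Character vector of variant identifiers.
#' @return Character vector of effect-allele letters (or `NA`).
#' @examples
#' effect_allele(c("rs1333049", "rs4977574"))
#' @export
effect_allele <- function(variant) {
  map <- c(rs1333049 = "C", rs4977574 = "G")
  unname(map[variant])
}

#' Read a study-level genotype-count table
#'
#' Reads a CSV of case-control genotype counts (one row per
#' study-variant) into a validated `study_set` data frame.  The literal
#' string `"NA"` in `control_source` is a real stratum (source not
#' stated) and is preserved, not parsed as missing.
#'
#' @param path Path to a CSV file with (at least) the columns
#'   `study_id, author, year, origin, variant, phenotype, ethnicity,
#'   control_source, case_hom_effect, case_het, case_hom_other,
#'   ctrl_hom_effect, ctrl_het, ctrl_hom_other, method`.  Extra columns
#'   are kept.
#' @param variant Optional variant identifier; if given, only matching
#'   rows are returned.
#' @return A data frame of class `study_set`, rows in file order.
#' @seealso [cdkn2b_studies()] for the packaged fixture,
#'   [write_studies()] for the inverse.
#' @export
read_studies <- function(path, variant = NULL) {
  if (!file.exists(path)) {
    stop("study file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character", na.strings = character())
  missing_cols <- setdiff(STUDY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("study file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c(COUNT_COLUMNS, "year")) {
    val <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(val) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-integer value in column '", col, "' at data row ",
           bad[1], " (study_id ", raw$study_id[bad[1]], ")")
    }
    raw[[col]] <- val
  }
  neg <- which(apply(raw[COUNT_COLUMNS] < 0, 1, any))
  if (length(neg) > 0) {
    stop("negative genotype count at data row ", neg[1],
         " (study_id ", raw$study_id[neg[1]], ")")
  }
  if (!is.null(variant)) {
    raw <- raw[raw$variant == variant, , drop = FALSE]
    rownames(raw) <- NULL
  }
  as_study_set(raw)
}

#' Write a study set back to CSV
#'
#' Inverse of [read_studies()]: `read_studies(write_studies(x, f))`
#' reproduces `x` field for field.
#'
#' @param set A `study_set` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(set, path) {
  utils::write.csv(set, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_study_set <- function(df) {
  dup <- unique(df$study_id[duplicated(df$study_id)])
  if (length(dup) > 0) {
    stop("duplicate study_id: ", paste(dup, collapse = ", "))
  }
  class(df) <- c("study_set", "data.frame")
  df
}

#' The CDKN2B-AS1 coronary heart disease study table
#'
#' The packaged fixture: 50 case-control study rows (33 for rs1333049,
#' 17 for rs4977574) with per-arm genotype counts, ethnicity, control
#' source and phenotype strata, transcribed from the source
#' meta-analysis study-characteristics table.  Genotype columns are
#' ordered effect-allele homozygote, heterozygote, other homozygote
#' (effect allele C for rs1333049, G for rs4977574).  The extra column
#' `hwe_printed` carries the control Hardy-Weinberg P value as
#' originally printed, for cross-checking against [hwe_test()].
#'
#' @param variant Optional variant filter (`"rs1333049"` or
#'   `"rs4977574"`).
#' @return A `study_set` data frame (50, 33 or 17 rows).
#' @examples
#' nrow(cdkn2b_studies("rs1333049"))
#' @export
cdkn2b_studies <- function(variant = NULL) {
  path <- system.file("extdata", "table1_cdkn2b_as1.csv",
                      package = "gcmeta", mustWork = TRUE)
  read_studies(path, variant = variant)
}

#' Validate study records
#'
#' Consistency findings (not errors) for each record: negative counts,
#' and — when the set carries declared totals in columns `n_cases` /
#' `n_controls` — disagreement between declared and summed counts.
#'
#' @param set A `study_set` data frame (or any data frame with the
#'   schema columns).
#' @return A data frame with columns `study_id`, `field`, `finding`;
#'   zero rows when everything is consistent.
#' @export
validate_studies <- function(set) {
  findings <- list()
  note <- function(id, field, msg) {
    findings[[length(findings) + 1]] <<- data.frame(
      study_id = id, field = field, finding = msg,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(set))) {
    r <- set[i, ]
    for (col in COUNT_COLUMNS) {
      if (is.na(r[[col]]) || r[[col]] < 0) {
        note(r$study_id, col, "count missing or negative")
      }
    }
    case_n <- r$case_hom_effect + r$case_het + r$case_hom_other
    ctrl_n <- r$ctrl_hom_effect + r$ctrl_het + r$ctrl_hom_other
    if (!is.null(set$n_cases) && !is.na(r$n_cases) && !is.na(case_n) &&
        r$n_cases != case_n) {
      note(r$study_id, "n_cases",
           sprintf("declared %d but genotype counts sum to %d", r$n_cases, case_n))
    }
    if (!is.null(set$n_controls) && !is.na(r$n_controls) && !is.na(ctrl_n) &&
        r$n_controls != ctrl_n) {
      note(r$study_id, "n_controls",
           sprintf("declared %d but genotype counts sum to %d", r$n_controls, ctrl_n))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(study_id = character(), field = character(),
                      finding = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Case, control and study totals of a set
#'
#' @param set A `study_set` data frame.
#' @return A list with `n_cases`, `n_controls` (persons) and `k`
#'   (number of study rows).
#' @examples
#' study_totals(cdkn2b_studies("rs1333049"))
#' @export
study_totals <- function(set) {
  list(
    n_cases = sum(set$case_hom_effect + set$case_het + set$case_hom_other),
    n_controls = sum(set$ctrl_hom_effect + set$ctrl_het + set$ctrl_hom_other),
    k = nrow(set)
  )
}

#' @export
print.study_set <- function(x, ...) {
  tot <- study_totals(x)
  cat(sprintf("study_set: %d record(s), %d cases / %d controls\n",
              tot$k, tot$n_cases, tot$n_controls))
  if (nrow(x) > 0) {
    cat("variants:", paste(unique(x$variant), collapse = ", "), "\n")
  }
  NextMethod()
  invisible(x)
}
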