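# Cohort data dictionary, validation, and delimited-text I/O.

#' Cohort data dictionary
#'
#' Canonical column names, types and category sets for a person-level cohort
#' table. Every other module assumes tables conform to this dictionary; user
#' files with different headers can be mapped onto it via the `mapping`
#' argument of [read_cohort()].
#'
#' @return A list with elements `columns` (character vector of canonical
#'   column names in canonical order), `levels` (named list of allowed levels
#'   for each categorical column) and `schema_version`.
#' @export
cohort_dictionary <- function() {
  list(
    columns = c(
      "pid", "site", "age", "sex", "height", "weight", "walk_time_10m",
      "education", "marital", "assets", "smoking", "alcohol",
      "phys_activity", "impairments", "dementia", "depression",
      "diabetes", "stroke"
    ),
    levels = list(
      sex           = c("female", "male"),
      education     = c("none", "incomplete_primary", "primary",
                        "secondary", "tertiary"),
      marital       = c("never", "married_cohab", "widowed", "divorced_sep"),
      smoking       = c("never", "ever"),
      alcohol       = c("none_or_heavy", "moderate"),
      phys_activity = c("low", "high"),
      impairments   = c("none", "one_two", "three_plus")
    ),
    schema_version = "1.0"
  )
}

#' Default site labels
#'
#' The nine shipped site labels: six countries, three of them with an urban
#' and a rural catchment area.
#'
#' @return Character vector of site labels.
#' @export
default_sites <- function() {
  c("cuba", "dominican_republic", "peru_urban", "peru_rural",
    "mexico_urban", "mexico_rural", "china_urban", "china_rural",
    "puerto_rico")
}

# per-row invariant checks; returns data.frame(pid, field, reason), 0 rows if ok
validate_rows <- function(df, sites = NULL, dict = cohort_dictionary()) {
  rej <- list()
  bad <- function(mask, field, reason) {
    mask[is.na(mask)] <- FALSE
    if (any(mask)) {
      rej[[length(rej) + 1L]] <<- data.frame(
        pid = as.character(df$pid[mask]), field = field, reason = reason,
        stringsAsFactors = FALSE
      )
    }
  }
  bad(is.na(df$pid) | df$pid == "", "pid", "missing pid")
  dup <- duplicated(df$pid) | duplicated(df$pid, fromLast = TRUE)
  bad(dup & !is.na(df$pid), "pid", "duplicate pid")
  bad(is.na(df$age), "age", "missing age")
  bad(df$age < 65, "age", "age < 65")
  bad(is.na(df$height), "height", "missing height")
  bad(df$height <= 1.0 | df$height >= 2.2, "height",
      "height outside (1.0, 2.2) m")
  bad(!is.na(df$weight) & (df$weight <= 25 | df$weight >= 250), "weight",
      "weight outside (25, 250) kg")
  bad(!is.na(df$walk_time_10m) & df$walk_time_10m <= 0, "walk_time_10m",
      "walk time <= 0")
  bad(is.na(df$assets) | df$assets < 0 | df$assets > 7 |
        df$assets != round(df$assets), "assets", "assets not in 0..7")
  if (!is.null(sites)) bad(!(df$site %in% sites), "site", "unknown site")
  for (v in names(dict$levels)) {
    bad(is.na(df[[v]]) | !(df[[v]] %in% dict$levels[[v]]), v,
        paste0(v, " not in {", paste(dict$levels[[v]], collapse = ", "), "}"))
  }
  for (v in c("dementia", "depression", "diabetes", "stroke")) {
    bad(is.na(df[[v]]) | !(df[[v]] %in% c(0, 1)), v, "flag not 0/1")
  }
  if (length(rej) == 0L) {
    data.frame(pid = character(0), field = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rej)
  }
}

#' Construct a validated cohort table
#'
#' Checks a data.frame against the data dictionary and the row-level
#' invariants (age >= 65, height in (1.0, 2.2) m, weight in (25, 250) kg when
#' present, positive walk time, categorical levels, unique pid). Rows failing
#' any invariant are removed from the returned table and collected into a
#' rejects report (attribute `"rejects"`), never silently dropped.
#'
#' @param df data.frame with the canonical columns of [cohort_dictionary()].
#' @param sites allowed site labels; `NULL` accepts any label.
#' @param provenance free-text source tag stored on the result.
#' @return A `cohort` object: the validated data.frame with attributes
#'   `rejects` (data.frame pid/field/reason), `provenance` and
#'   `schema_version`.
#' @export
as_cohort <- function(df, sites = NULL, provenance = "unspecified") {
  dict <- cohort_dictionary()
  missing_cols <- setdiff(dict$columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, dict$columns, drop = FALSE]
  df$pid <- as.character(df$pid)
  df$site <- as.character(df$site)
  for (v in c("age", "height", "weight", "walk_time_10m", "assets",
              "dementia", "depression", "diabetes", "stroke")) {
    df[[v]] <- as.numeric(df[[v]])
  }
  rejects <- validate_rows(df, sites = sites, dict = dict)
  keep <- !(df$pid %in% rejects$pid)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            rejects = rejects,
            provenance = provenance,
            schema_version = dict$schema_version,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort table: %d records, %d sites (schema %s)\n",
              nrow(x), length(unique(x$site)), attr(x, "schema_version")))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0L) {
    cat(sprintf("  %d rejected row(s); see attr(x, \"rejects\")\n", nrow(rej)))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more record(s)\n", nrow(x) - 6L))
  invisible(x)
}

#' Rejects report of a cohort
#'
#' @param table a `cohort` object.
#' @return data.frame with columns pid, field, reason (0 rows if none).
#' @export
cohort_rejects <- function(table) {
  attr(table, "rejects")
}

#' Read a person-level cohort from delimited text
#'
#' Reads a delimited file (UTF-8; empty fields are missing values), optionally
#' renames columns onto the canonical dictionary names, and validates every
#' row. Invalid rows are reported via the rejects attribute of the result.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @param mapping optional named character vector `c(canonical = "file_name")`
#'   mapping dictionary names to the file's header names.
#' @param sites allowed site labels; `NULL` accepts any.
#' @return A `cohort` object (see [as_cohort()]).
#' @export
read_cohort <- function(path, sep = ",", mapping = NULL, sites = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      idx <- match(mapping[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  as_cohort(df, sites = sites, provenance = path)
}

#' Write a cohort table as delimited text
#'
#' Canonical column order; missing values serialised as empty fields (not
#' "NA" text). `write_cohort()` then `read_cohort()` is the identity on valid
#' tables, and write-read-write is byte-idempotent.
#'
#' @param table a `cohort` object or conforming data.frame.
#' @param path output path.
#' @param sep field delimiter.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path, sep = ",") {
  cols <- cohort_dictionary()$columns
  df <- as.data.frame(table)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive table by case status
#'
#' Column percentages of each categorical variable within case-status groups
#' (no sarcopenia / sarcopenia only / sarcopenic obesity), per site, with a
#' chi-square group-comparison p-value (no continuity correction). A warning
#' column records when any expected cell count is below 5; with fewer than two
#' non-empty groups the p-value is omitted with a warning.
#'
#' @param table cohort data.frame.
#' @param grouping factor/character vector (length `nrow(table)`) assigning
#'   each record to `no_sarcopenia`, `sarcopenia_only` or
#'   `sarcopenic_obesity`; `NA` records are excluded.
#' @param variables categorical variables to tabulate (default: all
#'   dictionary categoricals plus banded assets).
#' @return data.frame with site, variable, category, one percentage column per
#'   group, group n's, p_value and expected_warning.
#' @export
describe_by_group <- function(table, grouping,
                              variables = c("sex", "education", "marital",
                                            "smoking", "alcohol",
                                            "phys_activity", "impairments")) {
  groups <- c("no_sarcopenia", "sarcopenia_only", "sarcopenic_obesity")
  stopifnot(length(grouping) == nrow(table))
  grouping <- as.character(grouping)
  keep <- !is.na(grouping)
  table <- table[keep, , drop = FALSE]
  grouping <- factor(grouping[keep], levels = groups)
  out <- list()
  for (s in sort(unique(table$site))) {
    in_site <- table$site == s
    g <- grouping[in_site]
    for (v in variables) {
      x <- factor(table[[v]][in_site],
                  levels = cohort_dictionary()$levels[[v]])
      tab <- table(x, g)
      pct <- prop.table(tab, margin = 2) * 100
      pct[, colSums(tab) == 0] <- NA_real_   # zero-member group: undefined
      nonempty <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(nonempty) >= 2L && nrow(nonempty) >= 2L &&
          sum(nonempty) > 0) {
        expected <- outer(rowSums(nonempty), colSums(nonempty)) /
          sum(nonempty)
        warn_exp <- any(expected < 5)
        p <- suppressWarnings(
          stats::chisq.test(nonempty, correct = FALSE)$p.value
        )
      } else {
        warning("site ", s, ", variable ", v,
                ": fewer than two non-empty groups; p-value omitted")
        p <- NA_real_
        warn_exp <- NA
      }
      block <- data.frame(
        site = s, variable = v, category = levels(x),
        stringsAsFactors = FALSE
      )
      for (j in seq_along(groups)) {
        block[[paste0("pct_", groups[j])]] <- as.numeric(pct[, j])
        block[[paste0("n_", groups[j])]] <- as.integer(colSums(tab))[j]
      }
      block$p_value <- p
      block$expected_warning <- warn_exp
      out[[length(out) + 1L]] <- block
    }
  }
  do.call(rbind, out)
}
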