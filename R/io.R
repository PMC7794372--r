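#' @keywords internal
#' @noRd
measurement_cols <- c("web_id", "species", "location",
                      "d_v_mm", "d_h_mm", "r_u_mm", "r_r_mm", "H_mm",
                      "s_q1", "s_q2", "s_q3", "s_q4",
                      "n_radii", "n_frame", "n_mooring")

morphology_cols <- c("spider_id", "web_id", "species", "location",
                     "total_length_mm", "ceph_width_mm",
                     "pt_leg1_mm", "pt_leg3_mm")

empty_measurements <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 3),
                               measurement_cols[1:3]))
  for (nm in measurement_cols[-(1:3)]) df[[nm]] <- numeric(0)
  df
}

empty_morphology <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 4),
                               morphology_cols[1:4]))
  for (nm in morphology_cols[-(1:4)]) df[[nm]] <- numeric(0)
  df
}

#' Validate a web-measurement table
#'
#' Checks every row against the physical invariants of an orb-web
#' measurement record: positive lengths, hub + free zone smaller than both
#' capture-spiral diameters (`H < min(d_v, d_h)`), measured radii inside
#' their diameters (so the derived lower/left radii are positive),
#' non-negative counts, and at least 3 radii for a valid orb.
#'
#' @param webs Data frame in the measurement schema.
#' @return A data frame of problems with columns `row`, `web_id`, `problem`;
#'   zero rows when the table is valid.
#' @export
validate_measurements <- function(webs) {
  problems <- list()
  note <- function(rows, what) {
    if (any(rows)) {
      problems[[length(problems) + 1]] <<- data.frame(
        row = which(rows), web_id = webs$web_id[rows], problem = what,
        stringsAsFactors = FALSE)
    }
  }
  num <- webs[, c("d_v_mm", "d_h_mm", "r_u_mm", "r_r_mm", "H_mm",
                  "s_q1", "s_q2", "s_q3", "s_q4",
                  "n_radii", "n_frame", "n_mooring")]
  bad_na <- !complete.cases(num)
  note(bad_na, "missing or non-numeric value")
  ok <- !bad_na
  note(ok & (webs$d_v_mm <= 0 | webs$d_h_mm <= 0 | webs$r_u_mm <= 0 |
               webs$r_r_mm <= 0), "non-positive length measurement")
  note(ok & webs$H_mm < 0, "negative hub diameter")
  note(ok & webs$H_mm >= pmin(webs$d_v_mm, webs$d_h_mm),
       "hub + free zone (H) not smaller than both diameters")
  note(ok & webs$r_u_mm >= webs$d_v_mm,
       "r_u >= d_v (derived lower radius would be non-positive)")
  note(ok & webs$r_r_mm >= webs$d_h_mm,
       "r_r >= d_h (derived left radius would be non-positive)")
  cnt <- webs[, c("s_q1", "s_q2", "s_q3", "s_q4",
                  "n_radii", "n_frame", "n_mooring")]
  note(ok & apply(cnt < 0, 1, any), "negative count")
  note(ok & webs$n_radii < 3, "fewer than 3 radii")
  if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(0), web_id = character(0),
               problem = character(0), stringsAsFactors = FALSE)
}

#' Validate a spider-morphology table
#'
#' @param spiders Data frame in the morphology schema.
#' @return A data frame of problems (`row`, `spider_id`, `problem`);
#'   zero rows when valid.
#' @export
validate_morphology <- function(spiders) {
  problems <- list()
  note <- function(rows, what) {
    if (any(rows)) {
      problems[[length(problems) + 1]] <<- data.frame(
        row = which(rows), spider_id = spiders$spider_id[rows],
        problem = what, stringsAsFactors = FALSE)
    }
  }
  num <- spiders[, c("total_length_mm", "ceph_width_mm",
                     "pt_leg1_mm", "pt_leg3_mm")]
  bad_na <- !complete.cases(num)
  note(bad_na, "missing or non-numeric value")
  ok <- !bad_na
  note(ok & apply(num <= 0, 1, any), "non-positive length measurement")
  note(ok & spiders$ceph_width_mm >= spiders$total_length_mm,
       "cephalothorax width not smaller than total length")
  if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(0), spider_id = character(0),
               problem = character(0), stringsAsFactors = FALSE)
}

read_table_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), cols)) {
    stop("malformed header in ", path, "\n  expected: ",
         paste(cols, collapse = ","), "\n  found:    ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  df
}

#' Read a web-measurement CSV
#'
#' The file must carry the exact documented header
#' `web_id,species,location,d_v_mm,d_h_mm,r_u_mm,r_r_mm,H_mm,s_q1,s_q2,s_q3,s_q4,n_radii,n_frame,n_mooring`
#' (comma-separated, UTF-8, `.` decimal, missing values as empty cells; all
#' lengths in mm). Rows violating the measurement invariants are dropped
#' with a warning; the full problem list is attached as
#' `attr(x, "validation")`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of valid measurement rows.
#' @export
read_measurements <- function(path) {
  df <- read_table_checked(path, measurement_cols)
  for (nm in measurement_cols[-(1:3)]) df[[nm]] <- as.numeric(df[[nm]])
  report <- validate_measurements(df)
  if (nrow(report)) {
    warning(nrow(report), " invalid measurement row(s) rejected from ",
            basename(path), " (see attr(x, 'validation'))", call. = FALSE)
    df <- df[-unique(report$row), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "validation") <- report
  df
}

#' Read a spider-morphology CSV
#'
#' Expected header:
#' `spider_id,web_id,species,location,total_length_mm,ceph_width_mm,pt_leg1_mm,pt_leg3_mm`.
#' Invalid rows are dropped with a warning and listed in
#' `attr(x, "validation")`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of valid morphology rows.
#' @export
read_morphology <- function(path) {
  df <- read_table_checked(path, morphology_cols)
  for (nm in morphology_cols[-(1:4)]) df[[nm]] <- as.numeric(df[[nm]])
  report <- validate_morphology(df)
  if (nrow(report)) {
    warning(nrow(report), " invalid morphology row(s) rejected from ",
            basename(path), " (see attr(x, 'validation'))", call. = FALSE)
    df <- df[-unique(report$row), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "validation") <- report
  df
}

#' Write measurement / morphology tables
#'
#' Plain CSV writers for the two schemas (comma-separated, UTF-8, `.`
#' decimal, no row names); `write_*` then `read_*` round-trips numerically.
#'
#' @param x Data frame in the corresponding schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  write.csv(x[, measurement_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
write_morphology <- function(x, path) {
  write.csv(x[, morphology_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
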