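#' @title Tabular schemas shared across the pipeline
#' @description
#' Every stage of the pipeline consumes and emits plain delimited-text
#' tables (comma separated, UTF-8, header row). Each table conforms to one
#' of the schemas listed by [ck_schemas()]; [read_table()] validates rows
#' against the schema's invariants on read and [write_table()] writes
#' tables that round-trip exactly.
#'
#' All dates are integer day offsets from a configurable epoch. ISO-8601
#' calendar dates in input files are converted on read when an `epoch` is
#' supplied. Group-membership intervals are half-open `[start_day,
#' end_day)` so co-residence day counts are plain interval intersections.
#' Missing values are empty fields, never sentinel numbers.
#' @name core_io
NULL

# field spec: type, required (non-NA), positive (strictly > 0 when present)
ck_field <- function(type, required = TRUE, positive = FALSE) {
  list(type = type, required = required, positive = positive)
}

.ck_schemas <- list(
  individual = list(
    fields = list(
      id          = ck_field("character"),
      sex         = ck_field("character"),
      birth_day   = ck_field("integer"),
      death_day   = ck_field("integer", required = FALSE),
      mother_id   = ck_field("character", required = FALSE),
      sire_id     = ck_field("character", required = FALSE),
      cohort      = ck_field("character", required = FALSE),
      natal_group = ck_field("character", required = FALSE)
    )
  ),
  membership = list(
    fields = list(
      id        = ck_field("character"),
      group     = ck_field("character"),
      start_day = ck_field("integer"),
      end_day   = ck_field("integer")
    )
  ),
  agonistic = list(
    fields = list(
      day       = ck_field("integer"),
      winner_id = ck_field("character"),
      loser_id  = ck_field("character")
    )
  ),
  affiliation = list(
    fields = list(
      day         = ck_field("integer"),
      protocol_id = ck_field("character"),
      focal_id    = ck_field("character"),
      partner_id  = ck_field("character")
    )
  ),
  protocol = list(
    fields = list(
      protocol_id  = ck_field("character"),
      focal_id     = ck_field("character"),
      day          = ck_field("integer"),
      duration_min = ck_field("numeric", positive = TRUE)
    )
  ),
  morpho = list(
    fields = list(
      id            = ck_field("character"),
      day           = ck_field("integer"),
      body_mass_kg  = ck_field("numeric", required = FALSE, positive = TRUE),
      crl_cm        = ck_field("numeric", required = FALSE, positive = TRUE),
      testis_len_mm = ck_field("numeric", required = FALSE, positive = TRUE),
      testis_wid_mm = ck_field("numeric", required = FALSE, positive = TRUE)
    )
  ),
  genotype = list(
    fields = list(
      id      = ck_field("character"),
      locus   = ck_field("character"),
      allele1 = ck_field("character"),
      allele2 = ck_field("character")
    )
  ),
  female_order = list(
    fields = list(
      position = ck_field("integer"),
      id       = ck_field("character")
    )
  ),
  rank_series = list(
    fields = list(
      id        = ck_field("character"),
      day       = ck_field("integer"),
      hierarchy = ck_field("character"),
      rank      = ck_field("numeric")
    )
  ),
  lrs = list(
    fields = list(
      id                = ck_field("character"),
      sex               = ck_field("character"),
      lrs               = ck_field("integer"),
      father_cores_days = ck_field("integer"),
      mother_cores_days = ck_field("integer"),
      mother_id         = ck_field("character"),
      sire_id           = ck_field("character"),
      cohort            = ck_field("character"),
      birth_group       = ck_field("character")
    )
  )
)

#' List the table schemas known to the pipeline
#' @return Character vector of schema names accepted by [read_table()].
#' @export
ck_schemas <- function() names(.ck_schemas)

ck_schema <- function(schema) {
  if (!schema %in% names(.ck_schemas)) {
    stop("unknown schema '", schema, "'; known: ",
         paste(ck_schemas(), collapse = ", "), call. = FALSE)
  }
  .ck_schemas[[schema]]
}

# convert a day column that may hold ISO-8601 dates to integer day offsets
.ck_to_day <- function(x, epoch, col) {
  if (is.numeric(x)) return(as.integer(round(x)))
  xe <- !is.na(x) & nzchar(x)
  out <- rep(NA_integer_, length(x))
  if (!any(xe)) return(out)
  num <- suppressWarnings(as.numeric(x[xe]))
  if (!anyNA(num)) {
    out[xe] <- as.integer(round(num))
    return(out)
  }
  if (is.null(epoch)) {
    stop("column '", col, "' holds calendar dates but no epoch was given",
         call. = FALSE)
  }
  d <- as.Date(x[xe], format = "%Y-%m-%d")
  if (anyNA(d)) stop("column '", col, "' has unparseable dates", call. = FALSE)
  out[xe] <- as.integer(d - as.Date(epoch))
  out
}

.ck_day_cols <- function(fields) {
  nm <- names(fields)
  nm[nm == "day" | grepl("_day$", nm)]
}

# per-schema row invariants; return character vector of messages, one per
# offending row, each prefixed "row <i>: "
.ck_row_checks <- function(schema, df) {
  msg <- function(rows, what) {
    if (!length(rows)) character(0) else paste0("row ", rows, ": ", what)
  }
  bad <- character(0)
  if (schema == "individual") {
    r <- which(!is.na(df$death_day) & df$birth_day >= df$death_day)
    bad <- c(bad, msg(r, "birth_day must precede death_day"))
    r <- which(!is.na(df$mother_id) & df$mother_id == df$id)
    bad <- c(bad, msg(r, "mother_id equals id"))
    r <- which(!is.na(df$sire_id) & df$sire_id == df$id)
    bad <- c(bad, msg(r, "sire_id equals id"))
    r <- which(!df$sex %in% c("female", "male"))
    bad <- c(bad, msg(r, "sex must be 'female' or 'male'"))
    if (anyDuplicated(df$id)) {
      bad <- c(bad, msg(which(duplicated(df$id)), "duplicate id"))
    }
  } else if (schema == "membership") {
    r <- which(df$start_day >= df$end_day)
    bad <- c(bad, msg(r, "start_day must precede end_day"))
    # intervals for one id must not overlap
    for (i in unique(df$id[duplicated(df$id)])) {
      rows <- which(df$id == i)
      o <- rows[order(df$start_day[rows])]
      ov <- o[-1][df$start_day[o[-1]] < df$end_day[o[-length(o)]]]
      bad <- c(bad, msg(ov, paste0("overlapping membership interval for id '",
                                   i, "'")))
    }
  } else if (schema == "agonistic") {
    r <- which(df$winner_id == df$loser_id)
    bad <- c(bad, msg(r, "winner_id equals loser_id"))
  } else if (schema == "affiliation") {
    r <- which(df$focal_id == df$partner_id)
    bad <- c(bad, msg(r, "focal_id equals partner_id"))
  } else if (schema == "protocol") {
    key <- paste(df$focal_id, df$day)
    r <- which(duplicated(key))
    bad <- c(bad, msg(r, "more than one protocol per focal per day"))
  } else if (schema == "morpho") {
    meas <- c("body_mass_kg", "crl_cm", "testis_len_mm", "testis_wid_mm")
    r <- which(rowSums(!is.na(df[meas])) == 0)
    bad <- c(bad, msg(r, "no measurement present"))
  } else if (schema == "genotype") {
    key <- paste(df$id, df$locus)
    r <- which(duplicated(key))
    bad <- c(bad, msg(r, "duplicate locus call for one id"))
  } else if (schema == "female_order") {
    if (anyDuplicated(df$id)) {
      bad <- c(bad, msg(which(duplicated(df$id)), "duplicate id in order"))
    }
  } else if (schema == "rank_series") {
    r <- which(df$rank < 0 | df$rank > 1)
    bad <- c(bad, msg(r, "rank outside [0, 1]"))
    r <- which(!df$hierarchy %in% c("male", "female_immature"))
    bad <- c(bad, msg(r, "hierarchy must be 'male' or 'female_immature'"))
  } else if (schema == "lrs") {
    r <- which(df$lrs < 0)
    bad <- c(bad, msg(r, "lrs must be non-negative"))
    r <- which(df$father_cores_days < 0 | df$mother_cores_days < 0)
    bad <- c(bad, msg(r, "co-residence days must be non-negative"))
  }
  bad
}

#' Validate a table against one of the pipeline schemas
#'
#' Checks column presence and types, required (non-missing) fields,
#' positivity constraints, and the schema's row invariants (e.g. a winner
#' may not equal its loser; membership intervals for one individual may
#' not overlap). Errors cite the offending column or row number.
#'
#' @param df data.frame to validate.
#' @param schema schema name; one of [ck_schemas()].
#' @return `df`, column-ordered per the schema, invisibly usable.
#' @export
validate_table <- function(df, schema) {
  sc <- ck_schema(schema)
  fields <- sc$fields
  missing_cols <- setdiff(names(fields), names(df))
  if (length(missing_cols)) {
    stop("schema '", schema, "': missing column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  df <- df[names(fields)]
  for (col in names(fields)) {
    f <- fields[[col]]
    x <- df[[col]]
    if (f$type == "character") {
      x <- as.character(x)
      x[!is.na(x) & !nzchar(x)] <- NA_character_
    } else if (f$type == "integer") {
      if (!is.numeric(x)) {
        stop("schema '", schema, "': column '", col, "' must be numeric",
             call. = FALSE)
      }
      x <- as.integer(round(x))
    } else {
      if (!is.numeric(x) && !all(is.na(x))) {
        stop("schema '", schema, "': column '", col, "' must be numeric",
             call. = FALSE)
      }
      x <- as.numeric(x)
    }
    if (f$required && anyNA(x)) {
      stop("schema '", schema, "': row ", which(is.na(x))[1],
           ": required column '", col, "' is missing", call. = FALSE)
    }
    if (f$positive) {
      bad <- which(!is.na(x) & x <= 0)
      if (length(bad)) {
        stop("schema '", schema, "': row ", bad[1], ": column '", col,
             "' must be > 0", call. = FALSE)
      }
    }
    df[[col]] <- x
  }
  bad <- .ck_row_checks(schema, df)
  if (length(bad)) {
    stop("schema '", schema, "': ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  df
}

#' Read a validated pipeline table
#'
#' @param path path to a comma-separated UTF-8 file with a header row whose
#'   column names match the schema's field names.
#' @param schema schema name; one of [ck_schemas()].
#' @param epoch optional ISO date (`"YYYY-MM-DD"`). When given, day columns
#'   holding calendar dates are converted to integer day offsets from it.
#' @return data.frame of validated records, row order preserved.
#' @export
read_table <- function(path, schema, epoch = NULL) {
  sc <- ck_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(names(sc$fields), names(df))
  if (length(missing_cols)) {
    stop("schema '", schema, "': file ", path, " lacks column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  for (col in names(sc$fields)) {
    f <- sc$fields[[col]]
    if (col %in% .ck_day_cols(sc$fields)) {
      df[[col]] <- .ck_to_day(df[[col]], epoch, col)
    } else if (f$type != "character") {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  validate_table(df, schema)
}

#' Write a pipeline table as delimited text
#'
#' Inverse of [read_table()]: `read_table(write_table(x))` returns `x`
#' exactly. Missing values are written as empty fields.
#'
#' @param records validated data.frame of one schema.
#' @param path output file path.
#' @param schema schema name used to validate before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  records <- validate_table(as.data.frame(records), schema)
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# interval utilities -------------------------------------------------------

# total length of intersection of two sets of half-open intervals,
# each a data.frame/list with start, end vectors
.ck_interval_intersection <- function(s1, e1, s2, e2) {
  if (!length(s1) || !length(s2)) return(0L)
  tot <- 0L
  for (i in seq_along(s1)) {
    lo <- pmax(s1[i], s2)
    hi <- pmin(e1[i], e2)
    tot <- tot + sum(pmax(hi - lo, 0L))
  }
  as.integer(tot)
}

# days (as integer count) id was a member of `group` within [lo, hi)
.ck_days_in_group <- function(memberships, id, group, lo, hi) {
  m <- memberships[memberships$id == id & memberships$group == group, ,
                   drop = FALSE]
  .ck_interval_intersection(m$start_day, m$end_day, lo, hi)
}

# TRUE if id is a member of `group` on `day` (vectorized over day)
.ck_in_group_on <- function(memberships, id, group, day) {
  m <- memberships[memberships$id == id & memberships$group == group, ,
                   drop = FALSE]
  if (!nrow(m)) return(rep(FALSE, length(day)))
  out <- rep(FALSE, length(day))
  for (i in seq_len(nrow(m))) {
    out <- out | (day >= m$start_day[i] & day < m$end_day[i])
  }
  out
}

#' Read a pipeline configuration file
#'
#' YAML file holding the epoch, age-window definitions and stage
#' parameters. Values omitted from the file fall back to
#' [default_config()].
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Default pipeline configuration
#'
#' The defaults encode the stated study design: one birth cohort of 55
#' focal subjects observed over 1552 days, weekly 20-min focal protocols,
#' a base affiliation rate of 1.78 events per protocol day, the age
#' windows used by the analyses (infancy `[0, 365)`, immaturity
#' `[0, 1461)`), the standard ages 90/455/1552 days, Elo defaults
#' (start 1000, k = 100), and paternity thresholds (males older than 1250
#' days, present at least 200 days before a birth, a minimum of 12 shared
#' loci).
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    epoch = "2004-10-01",
    seed = 1L,
    elo_k = 100,
    elo_start = 1000,
    singleton_rank = 1,
    window_infancy = c(0L, 365L),
    window_immaturity = c(0L, 1461L),
    standard_age_p1 = c(90L, 455L),
    standard_age_p2 = c(90L, 1552L),
    occasion_windows = list(infant = c(10L, 136L),
                            juvenile = c(407L, 517L),
                            adolescent = c(1502L, 1588L)),
    n_perm = 1000L,
    survival_days = 365L,
    cap_days = 1461L,
    min_shared_loci = 12L,
    sire_age_days = 1250L,
    sire_presence_days = 200L,
    sim = sim_config()
  )
}
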