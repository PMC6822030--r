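#' Build a trap array
#'
#' A trap array describes the camera-trap design of one survey session: one
#' detector per site (paired cameras photographing the two flanks of an animal
#' at the same passage count as a single proximity detector), planar projected
#' coordinates in meters, and a binary site-by-occasion activity mask.
#'
#' @param site_id character vector of unique site identifiers.
#' @param x,y numeric site coordinates in meters (projected planar CRS).
#' @param activity binary matrix, sites in rows and capture occasions in
#'   columns; 1 marks an operational site-occasion. Defaults to a single
#'   fully-active occasion.
#' @param cell_size optional design cell side in meters (metadata only).
#' @return An object of class `trap_array` with elements `site_id`, `x`, `y`,
#'   `activity` and `cell_size`.
#' @export
trap_array <- function(site_id, x, y, activity = NULL, cell_size = NA_real_) {
  site_id <- as.character(site_id)
  J <- length(site_id)
  if (anyDuplicated(site_id)) {
    dup <- site_id[duplicated(site_id)][1]
    abort_validation(sprintf("duplicate site id '%s'", dup), "scrdens_duplicate_site")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != J || length(y) != J)
    abort_validation("site_id, x and y must have equal length")
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    abort_validation(sprintf("non-finite coordinate at row %d", bad[1]),
                     "scrdens_bad_coordinate")
  if (is.null(activity)) activity <- matrix(1L, J, 1L)
  activity <- as.matrix(activity)
  storage.mode(activity) <- "integer"
  if (nrow(activity) != J)
    abort_validation("activity must have one row per site")
  if (!all(activity %in% c(0L, 1L)))
    abort_validation("activity entries must be 0 or 1")
  never <- which(rowSums(activity) == 0)
  if (length(never))
    abort_validation(sprintf("site '%s' has no active occasion", site_id[never[1]]))
  rownames(activity) <- site_id
  structure(list(site_id = site_id, x = x, y = y, activity = activity,
                 cell_size = as.numeric(cell_size)),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat(sprintf("Trap array: %d sites, %d occasions (%.0f site-occasions active)\n",
              length(x$site_id), ncol(x$activity), sum(x$activity)))
  cat(sprintf("  extent: x [%.0f, %.0f] m, y [%.0f, %.0f] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

n_occasions <- function(traps) ncol(traps$activity)

#' Build an encounter-history object
#'
#' Binary detections of identified individuals indexed individual x site x
#' occasion. A detection can only occur on an active site-occasion, and every
#' retained individual must carry at least one detection (undetected
#' individuals are unobservable in a capture-recapture survey).
#'
#' @param y binary array, individuals x sites x occasions.
#' @param traps the [trap_array()] the detections refer to.
#' @param sex per-individual sex labels in `c("F", "M", "U")`; defaults to all
#'   unknown.
#' @param session_id session label.
#' @return An object of class `encounter_data`.
#' @export
encounter_data <- function(y, traps, sex = NULL, session_id = "S1") {
  stopifnot(inherits(traps, "trap_array"))
  y <- as.array(y)
  if (length(dim(y)) != 3)
    abort_validation("y must be a 3-d array (individual x site x occasion)")
  n <- dim(y)[1]
  if (dim(y)[2] != length(traps$site_id) || dim(y)[3] != n_occasions(traps))
    abort_validation("dimensions of y do not match the trap array")
  storage.mode(y) <- "integer"
  if (!all(y %in% c(0L, 1L)))
    abort_validation("y entries must be 0 or 1")
  if (n > 0) {
    act <- aperm(array(traps$activity, c(dim(y)[2], dim(y)[3], n)), c(3, 1, 2))
    if (any(y == 1L & act == 0L))
      abort_validation("detection recorded on an inactive site-occasion",
                       "scrdens_inactive_detection")
    if (any(apply(y, 1, sum) == 0))
      abort_validation("every individual must have at least one detection")
  }
  if (is.null(sex)) sex <- rep("U", n)
  sex <- as.character(sex)
  if (length(sex) != n || !all(sex %in% c("F", "M", "U")))
    abort_validation("sex must be one of F, M, U per individual")
  if (is.null(dimnames(y)[[1]]))
    dimnames(y)[[1]] <- if (n) sprintf("ind%03d", seq_len(n)) else character(0)
  dimnames(y)[[2]] <- traps$site_id
  structure(list(individuals = dimnames(y)[[1]], sex = sex, y = y,
                 session_id = as.character(session_id)),
            class = "encounter_data")
}

#' @export
print.encounter_data <- function(x, ...) {
  cat(sprintf("Encounter data '%s': %d individuals, %d detections, %d sites x %d occasions\n",
              x$session_id, dim(x$y)[1], sum(x$y), dim(x$y)[2], dim(x$y)[3]))
  if (dim(x$y)[1]) {
    tab <- table(factor(x$sex, levels = c("F", "M", "U")))
    cat(sprintf("  sex: %d F, %d M, %d unknown\n", tab["F"], tab["M"], tab["U"]))
  }
  invisible(x)
}

n_detections <- function(enc) sum(enc$y)

#' Bundle survey sessions with a parameter-sharing structure
#'
#' Multi-session fits share the detection parameters (`p0`, `sigma`) within
#' each sharing group while density is always estimated separately per
#' session. Sharing detection parameters across sessions with few detected
#' individuals increases the effective sample size.
#'
#' @param sessions list of sessions, each a list with elements `traps`
#'   ([trap_array()]) and `encounters` ([encounter_data()]).
#' @param sharing vector (one entry per session) assigning each session to a
#'   detection-parameter group; defaults to one group per session.
#' @return An object of class `session_set`.
#' @export
session_set <- function(sessions, sharing = NULL) {
  if (inherits(sessions, "session_set")) return(sessions)
  stopifnot(is.list(sessions), length(sessions) >= 1)
  for (s in sessions) {
    if (!inherits(s$traps, "trap_array") || !inherits(s$encounters, "encounter_data"))
      abort_validation("each session needs $traps (trap_array) and $encounters (encounter_data)")
  }
  S <- length(sessions)
  if (is.null(sharing)) sharing <- seq_len(S)
  if (length(sharing) != S)
    abort_validation("sharing must assign exactly one group per session")
  groups <- factor(sharing, levels = unique(sharing))
  labels <- vapply(sessions, function(s) s$encounters$session_id, character(1))
  structure(list(sessions = sessions, sharing = groups, labels = labels),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("Session set: %d sessions, %d detection-sharing group(s)\n",
              length(x$sessions), nlevels(x$sharing)))
  for (i in seq_along(x$sessions))
    cat(sprintf("  %s (group %s): %d individuals\n", x$labels[i],
                as.character(x$sharing[i]), dim(x$sessions[[i]]$encounters$y)[1]))
  invisible(x)
}

#' Map trap days to capture occasions
#'
#' Occasion `k` covers days `(k-1)*L + 1` through `k*L`; a survey of `D` days
#' yields `ceiling(D / L)` occasions, a trailing occasion shorter than `L`
#' days being retained rather than dropped.
#'
#' @param day integer day indices, starting at 1 within the session.
#' @param occasion_length occasion length in trap days (default 5).
#' @return Integer occasion indices.
#' @export
day_to_occasion <- function(day, occasion_length = 5) {
  if (occasion_length < 1)
    abort_validation("occasion_length must be >= 1")
  day <- as.integer(day)
  if (any(day < 1)) abort_validation("day indices must start at 1")
  as.integer(ceiling(day / occasion_length))
}

#' Collapse daily records to capture occasions
#'
#' Aggregates daily detection and activity records into occasions of
#' `occasion_length` successive trap nights. A site-occasion is active if at
#' least one of its days is active; an individual is detected in an occasion
#' if it was photographed on at least one of its days, so repeated
#' photographs within an occasion collapse to a single binary entry.
#'
#' @param y_daily binary array individuals x sites x days (may have 0
#'   individuals).
#' @param activity_daily binary matrix sites x days.
#' @param occasion_length days per occasion (default 5).
#' @return list with collapsed `y` (individuals x sites x occasions) and
#'   `activity` (sites x occasions).
#' @export
collapse_occasions <- function(y_daily, activity_daily, occasion_length = 5) {
  if (occasion_length < 1)
    abort_validation("occasion_length must be >= 1")
  activity_daily <- as.matrix(activity_daily)
  D <- ncol(activity_daily)
  occ <- day_to_occasion(seq_len(D), occasion_length)
  K <- max(occ)
  J <- nrow(activity_daily)
  activity <- vapply(seq_len(K), function(k)
    as.integer(rowSums(activity_daily[, occ == k, drop = FALSE]) > 0),
    integer(J))
  activity <- matrix(activity, J, K, dimnames = list(rownames(activity_daily), NULL))
  y_daily <- as.array(y_daily)
  n <- dim(y_daily)[1]
  y <- array(0L, c(n, J, K), dimnames = c(dimnames(y_daily)[1:2], list(NULL)))
  for (k in seq_len(K)) {
    slab <- y_daily[, , occ == k, drop = FALSE]
    y[, , k] <- as.integer(apply(slab, c(1, 2), max))
  }
  list(y = y, activity = activity)
}

parse_delim <- function(path, sep = ",") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    abort_validation(sprintf("ragged row %d: %d fields where header has %d",
                             bad, nf[bad], nf[1]), "scrdens_ragged_row")
  }
  header <- trimws(fields[[1]])
  body <- fields[-1]
  df <- as.data.frame(do.call(rbind, lapply(body, trimws)),
                      stringsAsFactors = FALSE)
  if (!length(body)) df <- as.data.frame(matrix(character(0), 0, length(header)),
                                         stringsAsFactors = FALSE)
  names(df) <- header
  df
}

num_col <- function(df, col) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    abort_validation(sprintf("non-numeric value '%s' at row %d, column '%s'",
                             df[[col]][bad[1]], bad[1], col),
                     "scrdens_bad_coordinate")
  v
}

#' Read a trap-deployment table
#'
#' Expects a delimited text file with header columns `site,x,y` followed by
#' activity flags: either daily columns `d1..dD` (collapsed to occasions with
#' [collapse_occasions()]) or occasion columns `o1..oK`. Coordinates must be
#' planar meters; coordinates that all fall inside the geographic
#' longitude/latitude range are rejected because the model's distances are
#' Euclidean meters.
#'
#' @param path file path.
#' @param occasion_length days per occasion used when daily columns are
#'   present (default 5).
#' @param sep field delimiter.
#' @param cell_size optional design cell size in meters, stored as metadata.
#' @return A [trap_array()].
#' @export
read_traps <- function(path, occasion_length = 5, sep = ",", cell_size = NA_real_) {
  df <- parse_delim(path, sep)
  if (is.null(df) || !all(c("site", "x", "y") %in% names(df)))
    abort_validation("trap file must have header columns site,x,y")
  site <- as.character(df$site)
  if (anyDuplicated(site))
    abort_validation(sprintf("duplicate site id '%s' at row %d",
                             site[duplicated(site)][1],
                             which(duplicated(site))[1]),
                     "scrdens_duplicate_site")
  x <- num_col(df, "x"); y <- num_col(df, "y")
  if (length(x) > 1 && all(abs(x) <= 180) && all(abs(y) <= 90))
    abort_validation(paste("coordinates look like geographic lon/lat;",
                           "supply projected planar coordinates in meters"),
                     "scrdens_geographic_coords")
  day_cols <- grep("^d[0-9]+$", names(df), value = TRUE)
  occ_cols <- grep("^o[0-9]+$", names(df), value = TRUE)
  read_mask <- function(cols) {
    m <- sapply(cols, function(cl) {
      v <- suppressWarnings(as.integer(df[[cl]]))
      bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
      if (length(bad))
        abort_validation(sprintf("activity value '%s' at row %d, column '%s' is not 0/1",
                                 df[[cl]][bad[1]], bad[1], cl))
      v
    })
    matrix(m, nrow = nrow(df))
  }
  if (length(day_cols)) {
    ord <- order(as.integer(sub("^d", "", day_cols)))
    daily <- read_mask(day_cols[ord])
    activity <- collapse_occasions(array(0L, c(0, nrow(df), ncol(daily))),
                                   daily, occasion_length)$activity
  } else if (length(occ_cols)) {
    ord <- order(as.integer(sub("^o", "", occ_cols)))
    activity <- read_mask(occ_cols[ord])
  } else {
    activity <- NULL
  }
  trap_array(site, x, y, activity, cell_size = cell_size)
}

#' Write a trap-deployment table
#'
#' Writes the occasion-level dialect read back by [read_traps()]
#' (`site,x,y,o1..oK`).
#'
#' @param traps a [trap_array()].
#' @param path output file path.
#' @export
write_traps <- function(traps, path) {
  K <- n_occasions(traps)
  # full double precision so that write/read round-trips are exact
  df <- data.frame(site = traps$site_id,
                   x = sprintf("%.17g", traps$x),
                   y = sprintf("%.17g", traps$y),
                   traps$activity, check.names = FALSE)
  names(df)[-(1:3)] <- paste0("o", seq_len(K))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an encounter table
#'
#' Expects delimited text with header columns
#' `session,individual,day|occasion,site[,sex]`. With a `day` column, days
#' are collapsed into occasions of `occasion_length` trap nights. Repeated
#' records of an individual at a site within one occasion collapse to a
#' single binary detection, dissociating trapping events from individual
#' photographs to avoid pseudo-replication.
#'
#' @param path file path.
#' @param traps the [trap_array()] of the same session; defines sites and the
#'   activity mask.
#' @param occasion_length days per occasion when a `day` column is present.
#' @param sep field delimiter.
#' @param session session label to select when the file holds several;
#'   defaults to the single label present.
#' @param on_inactive what to do with a detection on an inactive
#'   site-occasion: `"error"` (default) or `"drop"` (warn and discard).
#' @param drop_individuals optional individual ids to exclude (e.g. records
#'   flagged unreliable upstream).
#' @return An [encounter_data()].
#' @export
read_encounters <- function(path, traps, occasion_length = 5, sep = ",",
                            session = NULL, on_inactive = c("error", "drop"),
                            drop_individuals = NULL) {
  on_inactive <- match.arg(on_inactive)
  df <- parse_delim(path, sep)
  K <- n_occasions(traps)
  J <- length(traps$site_id)
  if (is.null(df) || nrow(df) == 0) {
    return(encounter_data(array(0L, c(0, J, K)), traps,
                          session_id = session %||% "S1"))
  }
  need <- c("session", "individual", "site")
  if (!all(need %in% names(df)) || !any(c("day", "occasion") %in% names(df)))
    abort_validation("encounter file needs columns session,individual,day|occasion,site")
  if (is.null(session)) {
    ses <- unique(df$session)
    if (length(ses) > 1)
      abort_validation("file holds several sessions; pass `session` to select one")
    session <- ses
  }
  df <- df[df$session == session, , drop = FALSE]
  if (!is.null(drop_individuals))
    df <- df[!(df$individual %in% drop_individuals), , drop = FALSE]
  if ("occasion" %in% names(df)) {
    occ <- as.integer(num_col(df, "occasion"))
  } else {
    occ <- day_to_occasion(as.integer(num_col(df, "day")), occasion_length)
  }
  if (nrow(df) && any(occ < 1 | occ > K))
    abort_validation(sprintf("occasion %d at row %d outside 1..%d",
                             occ[which(occ < 1 | occ > K)[1]],
                             which(occ < 1 | occ > K)[1], K))
  jj <- match(df$site, traps$site_id)
  if (anyNA(jj))
    abort_validation(sprintf("unknown site id '%s' at row %d",
                             df$site[which(is.na(jj))[1]], which(is.na(jj))[1]),
                     "scrdens_unknown_site")
  inact <- which(traps$activity[cbind(jj, occ)] == 0L)
  if (length(inact)) {
    if (on_inactive == "error")
      abort_validation(sprintf("detection at inactive site-occasion (row %d, site '%s', occasion %d)",
                               inact[1], df$site[inact[1]], occ[inact[1]]),
                       "scrdens_inactive_detection")
    warning(sprintf("dropping %d detection(s) on inactive site-occasions", length(inact)))
    df <- df[-inact, , drop = FALSE]; jj <- jj[-inact]; occ <- occ[-inact]
  }
  ids <- unique(df$individual)
  y <- array(0L, c(length(ids), J, K),
             dimnames = list(ids, traps$site_id, NULL))
  y[cbind(match(df$individual, ids), jj, occ)] <- 1L
  sex <- rep("U", length(ids))
  if ("sex" %in% names(df)) {
    for (i in seq_along(ids)) {
      sx <- setdiff(unique(df$sex[df$individual == ids[i]]), c("", "U", NA))
      if (length(sx) > 1)
        abort_validation(sprintf("conflicting sex records for individual '%s'", ids[i]))
      if (length(sx) == 1) {
        if (!sx %in% c("F", "M"))
          abort_validation(sprintf("invalid sex '%s' for individual '%s'", sx, ids[i]))
        sex[i] <- sx
      }
    }
  }
  encounter_data(y, traps, sex = sex, session_id = session)
}

#' Write an encounter table
#'
#' One row per detection event (`session,individual,occasion,site,sex`), the
#' occasion-level dialect read back by [read_encounters()].
#'
#' @param enc an [encounter_data()].
#' @param path output file path.
#' @export
write_encounters <- function(enc, path) {
  idx <- which(enc$y == 1L, arr.ind = TRUE)
  df <- data.frame(session = enc$session_id,
                   individual = enc$individuals[idx[, 1]],
                   occasion = idx[, 3],
                   site = dimnames(enc$y)[[2]][idx[, 2]],
                   sex = enc$sex[idx[, 1]])
  df <- df[order(df$individual, df$occasion, df$site), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
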