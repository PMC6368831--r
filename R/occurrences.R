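occ_roles <- c("joint", "train", "test", "independent")

#' Read an occurrence CSV
#'
#' Expects a header row and the columns `species, longitude, latitude` in
#' that order (the layout used for `sp_joint.csv` and friends). Longitude and
#' latitude are not range-checked: values outside [-180, 180] / [-90, 90]
#' are accepted with a warning, since projected coordinate systems are
#' allowed.
#'
#' @param path CSV path.
#' @param role one of `"joint"`, `"train"`, `"test"`, `"independent"`.
#' @return an object of class `enm_occurrences` with fields `species`,
#'   `records` (data.frame of longitude/latitude) and `role`.
#' @export
read_occurrences <- function(path, role = "joint") {
  role <- match.arg(role, occ_roles)
  if (!file.exists(path))
    stop(sprintf("cannot read occurrences: no such file '%s'", path),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s': missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0)
    stop(sprintf("'%s': no occurrences", path), call. = FALSE)
  for (col in c("longitude", "latitude")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("'%s': non-numeric %s at data row %d", path, col, bad[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  if (any(abs(df$longitude) > 180 | abs(df$latitude) > 90))
    warning(sprintf("'%s': coordinates outside geographic bounds (projected CRS assumed)",
                    path), call. = FALSE)
  enm_occurrences(df$species[1], df$longitude, df$latitude, role)
}

#' Construct an occurrence set in memory
#' @param species species name.
#' @param longitude,latitude numeric coordinate vectors.
#' @param role one of `"joint"`, `"train"`, `"test"`, `"independent"`.
#' @export
enm_occurrences <- function(species, longitude, latitude, role = "joint") {
  role <- match.arg(role, occ_roles)
  if (length(longitude) != length(latitude) || length(longitude) < 1)
    stop("need at least one coordinate pair", call. = FALSE)
  if (any(!is.finite(longitude)) || any(!is.finite(latitude)))
    stop("coordinates must be finite", call. = FALSE)
  structure(list(species = as.character(species),
                 records = data.frame(longitude = longitude,
                                      latitude = latitude),
                 role = role),
            class = "enm_occurrences")
}

#' @export
print.enm_occurrences <- function(x, ...) {
  cat(sprintf("<enm_occurrences> %s: %d records (role: %s)\n",
              x$species, nrow(x$records), x$role))
  invisible(x)
}

#' Write an occurrence set as CSV
#' @param occ an `enm_occurrences`.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(
    data.frame(species = occ$species,
               longitude = occ$records$longitude,
               latitude = occ$records$latitude),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
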