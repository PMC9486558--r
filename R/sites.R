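#' Describe a recruiting centre's geography and clock rules
#'
#' @param name Site label.
#' @param latitude Degrees north (decimal), |latitude| <= 90.
#' @param longitude Degrees east (decimal), positive east, in (-180, 180].
#' @param utc_base_offset Hours east of UTC in winter, in \[-12, 14\].
#' @param dst_offset Additional hours while daylight saving is in force
#'   (0 or 1).
#' @param dst_rule `"EU"` (last Sunday of March to last Sunday of October)
#'   or `"none"`.
#' @return A one-row tibble usable wherever a site is expected.
#' @export
geo_site <- function(name, latitude, longitude, utc_base_offset,
                     dst_offset = 1, dst_rule = "EU") {
  stopifnot(
    abs(latitude) <= 90,
    longitude > -180, longitude <= 180,
    utc_base_offset >= -12, utc_base_offset <= 14,
    dst_offset %in% c(0, 1),
    dst_rule %in% c("EU", "none")
  )
  tibble::tibble(
    name = as.character(name), latitude = latitude, longitude = longitude,
    utc_base_offset = utc_base_offset, dst_offset = dst_offset,
    dst_rule = dst_rule
  )
}

#' The eight recruiting centres of the REQUITE breast cohort
#'
#' Geography as published for the cohort's eight European centres, all on
#' the EU daylight-saving calendar; Leicester is on UTC+0 in winter, the
#' continental sites on UTC+1.
#'
#' @return A tibble with one row per site, columns as in [geo_site()].
#' @export
requite_sites <- function() {
  tibble::tibble(
    name = c("Barcelona", "Gent", "Leicester", "Leuven",
             "Mannheim", "Milan", "Montpellier", "Santiago"),
    latitude = c(41.4, 51.1, 52.6, 50.9, 49.5, 45.5, 43.6, 42.9),
    longitude = c(-2.2, 3.7, -1.1, 4.7, 8.5, 9.2, 3.9, -8.5),
    utc_base_offset = c(1, 1, 0, 1, 1, 1, 1, 1),
    dst_offset = 1,
    dst_rule = "EU"
  )
}

#' Read a site table from delimited text
#'
#' Expects columns `name`, `latitude`, `longitude`, `utc_base_offset`,
#' `dst_offset`, `dst_rule`.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return A validated site tibble.
#' @export
read_sites <- function(path, sep = "\t") {
  x <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("name", "latitude", "longitude", "utc_base_offset",
            "dst_offset", "dst_rule")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("site table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    geo_site(x$name[i], x$latitude[i], x$longitude[i],
             x$utc_base_offset[i], x$dst_offset[i], x$dst_rule[i])
  }))
}
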