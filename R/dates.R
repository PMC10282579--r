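# Season/offset arithmetic.
#
# A breeding season for year y runs from 1 September of y-1 (the "anchor")
# to the response's reference date the following spring.  Windows are held
# on a grid of integer day offsets from the anchor so the same window can be
# laid onto every season; per-season calendar dates are anchor(y) + offset.
# Offset-to-label conversion uses a non-leap reference season.

season_anchor <- function(year) {
  as.Date(sprintf("%d-09-01", year - 1L))
}

# Day-of-year (non-leap convention) -> offset from the 1 Sept anchor.
# 1 Jan is offset 122 (30 + 31 + 30 + 31 days of Sept-Dec).
doy_to_offset <- function(doy) {
  as.integer(121L + doy)
}

offset_to_date <- function(year, offset) {
  season_anchor(year) + as.integer(offset)
}

# Human-readable calendar label for an offset ("14 Oct"), non-leap basis.
offset_label <- function(offset) {
  format(as.Date("2001-09-01") + as.integer(offset), "%e %b") |> trimws()
}

window_label <- function(open, close) {
  paste0(offset_label(open), "–", offset_label(close))
}
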