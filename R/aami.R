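# MIT-BIH beat symbol -> AAMI class grouping.
# N: normal, bundle-branch blocks, atrial/nodal escape.
# S: atrial premature (incl. aberrated), nodal premature, supraventricular premature.
# V: premature ventricular contraction, ventricular escape.
# F: fusion of ventricular and normal.
# Paced ('/'), fusion of paced and normal ('f') and unclassifiable ('Q') fall
# outside the four groups and are mapped to the excluded label "Q".
AAMI_TABLE <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q")

#' Map raw MIT-BIH beat symbols to AAMI classes
#'
#' Groups the database beat-type codes into the four AAMI classes N
#' (normal), S (supraventricular ectopic), V (ventricular ectopic) and F
#' (fusion). Codes outside the four groups -- paced beats, fusion of paced
#' and normal, unclassifiable beats -- map to the excluded label `"Q"`.
#' Unknown codes also map to `"Q"` with a warning; a beat is never silently
#' dropped, so the output always has the same length as the input.
#'
#' @param symbols Character vector of raw beat-type codes.
#' @return Character vector of labels in `c("N","S","V","F","Q")`, same
#'   length as `symbols`.
#' @export
map_aami <- function(symbols) {
  symbols <- as.character(symbols)
  if (!length(symbols)) return(character(0))
  out <- unname(AAMI_TABLE[symbols])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " unknown beat code(s) (",
            paste(unique(symbols[unknown]), collapse = ", "),
            ") mapped to excluded label 'Q'")
    out[unknown] <- "Q"
  }
  out
}

#' @rdname map_aami
#' @format NULL
#' @export
AAMI_CLASSES <- c("N", "S", "V", "F")
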