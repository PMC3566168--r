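#' Amino-acid alphabet in PSI-BLAST column order
#'
#' The canonical ordering `A R N D C Q E G H I L K M F P S T W Y V` used by
#' PSI-BLAST's ASCII PSSM output. All feature encodings in this package lay
#' their 20 per-residue columns out in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# padding symbol used at sequence termini; encoders map it to an all-zero row
PAD_CHAR <- "X"

METALS <- c("Fe", "Cu", "other")

.canon_metal <- function(metal) {
  metal <- as.character(metal)
  out <- ifelse(metal %in% c("Fe", "Cu"), metal, "other")
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
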