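# GRCh37 (hg19) chromosome lengths in base pairs, used to scale the
# genomic-overview x-axis and to place synthetic variants.
.GRCH37_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
)

#' GRCh37 chromosome lengths
#'
#' Named vector of nuclear chromosome lengths (bp) for reference build
#' GRCh37, in karyotype order 1-22, X, Y.
#'
#' @return named numeric vector of length 24.
#' @export
grch37_chromosome_lengths <- function() .GRCH37_LENGTHS
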