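# Condition vocabulary shared by every module. The screen has four modified
# baits, one unmodified bait ("C") and a beads-only control; order here is the
# canonical reporting order.

#' RNA modifications assayed by the bait panel
#'
#' The four cytosine-5 modifications carried by the RNA baits:
#' 5-methylcytidine (`m5C`), 5-hydroxymethylcytidine (`hm5C`),
#' 2'-O-methyl-5-hydroxymethylcytidine (`hm5Cm`) and 5-formylcytidine
#' (`f5C`). This order is the canonical column/reporting order throughout
#' the package.
#'
#' @return Character vector of the four modification labels.
#' @export
#' @examples
#' rna_modifications()
rna_modifications <- function() c("m5C", "hm5C", "hm5Cm", "f5C")

#' All pulldown conditions
#'
#' The six experimental conditions: the beads-only control (`beads`), the
#' unmodified cytosine bait (`C`), and the four modified baits from
#' [rna_modifications()].
#'
#' @return Character vector of length six.
#' @export
bait_conditions <- function() c("beads", "C", rna_modifications())

# internal: stop() with a prefixed, sprintf-formatted message
abort_mr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
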