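# Shared synthetic ground truths for inference tests.

truth_8edge <- function(strength = 1) {
  net <- data.frame(
    source = c("DUSP6", "DUSP6", "PPTC7", "PTPN1", "PTPN13", "PPP3CA",
               "DUSP10", "PTPN1"),
    target = c("PPTC7", "PTPN1", "PTPN13", "PPP3CA", "DUSP10", "DUSP6",
               "PPTC7", "DUSP10"),
    sign = c(1L, -1L, 1L, 1L, -1L, 1L, -1L, 1L),
    strength = strength,
    stringsAsFactors = FALSE)
  ground_truth(networks = net)
}

truth_empty <- function() ground_truth()

# signed edge keys of a ground truth at one time point
truth_edge_keys <- function(truth, time) {
  net <- truth$networks[[as.character(time)]]
  paste(net$source, net$target, net$sign)
}

called_edge_keys <- function(mn) {
  e <- mn$edges
  paste(e$source, e$target, e$sign)
}
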