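# Shared kite-at-reference-beta objects, computed once per test run.
.kite_cache <- new.env(parent = emptyenv())

kite_system <- function(beta = 0.534) {
  key <- paste0("sys_", beta)
  if (is.null(.kite_cache[[key]])) {
    .kite_cache[[key]] <- spin_system(make_kite(), beta = beta)
  }
  .kite_cache[[key]]
}

kite_op <- function(beta = 0.534) {
  key <- paste0("op_", beta)
  if (is.null(.kite_cache[[key]])) {
    .kite_cache[[key]] <- build_transfer_operator(kite_system(beta))
  }
  .kite_cache[[key]]
}

kite_flows <- function(beta = 0.534, tau_max = 300) {
  key <- paste0("flows_", beta, "_", tau_max)
  if (is.null(.kite_cache[[key]])) {
    .kite_cache[[key]] <- info_flow(kite_system(beta), tau_max = tau_max,
                                    op = kite_op(beta))
  }
  .kite_cache[[key]]
}

# mirror automorphism of the kite under the package labelling:
# 0<->1, 2<->4, 5<->6, others fixed (0-based)
kite_mirror <- c(1, 0, 4, 3, 2, 6, 5, 7, 8, 9)
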