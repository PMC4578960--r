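# Thin R wrappers around the C++ incremental-evaluation state.  A "state" is
# an external pointer holding the solution plus the window bookkeeping that
# makes single-cell toggles and best-gain scans cheap.  All randomness stays
# on the R side; the C++ layer is purely deterministic.

state_new <- function(grid, solution, w, Q, window) {
  zb_new(as.numeric(grid$eco), as.numeric(grid$dev),
         as.logical(grid$configurable),
         grid$n_rows, grid$n_cols, as.integer(window),
         as.logical(solution), as.numeric(w), as.numeric(Q))
}

state_solution <- function(st, grid) {
  matrix(zb_x(st), grid$n_rows, grid$n_cols)
}
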