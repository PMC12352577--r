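#' Ten-node worked-example connectome
#'
#' A small weighted network with two planted first-order cycles, used
#' throughout the documentation and tests as a fully tractable example.
#' Ten regions fall into three functional networks: FN1 = \{1\},
#' FN2 = \{2..6\}, FN3 = \{7..10\}. Edges carry five distinct positive
#' weight levels; absent edges have weight 0:
#'
#' * `0.9` -- the 5-cycle 2-3-4-5-6-2 (FN2's loop),
#' * `0.7` -- the 4-cycle 7-8-10-9-7 (FN3's loop),
#' * `0.5` -- chord 7-10, which triangulates and kills FN3's loop,
#' * `0.4` -- chords 2-4 and 4-6, which triangulate and kill FN2's loop,
#' * `0.2` -- connectors 1-2 and 6-7, which join the three components.
#'
#' Sweeping the six stages (the empty graph at `r = 1`, then the five
#' weight levels in decreasing order; the filtration runs on `d = 1 - w`)
#' gives clique-complex Betti sequences `b0 = (10, 6, 3, 3, 3, 1)` and
#' `b1 = (0, 1, 2, 1, 0, 0)`: FN2's 5-cycle persists over \[0.1, 0.6\] and
#' FN3's 4-cycle over \[0.3, 0.5\], so the 5-cycle is the more persistent.
#' Contracting by the partition yields a 3-super-node consolidated graph.
#'
#' @return list with `fc` (the [fc_matrix()]), `partition`
#'   (an `fn_partition` with classes FN1/FN2/FN3), `stage_r` (the six
#'   threshold stages, decreasing) and `cycles` (vertex lists of the two
#'   planted loops).
#' @export
example_connectome <- function() {
  edges <- rbind(
    c(2, 3, 0.9), c(3, 4, 0.9), c(4, 5, 0.9), c(5, 6, 0.9), c(2, 6, 0.9),
    c(7, 8, 0.7), c(8, 10, 0.7), c(9, 10, 0.7), c(7, 9, 0.7),
    c(7, 10, 0.5),
    c(2, 4, 0.4), c(4, 6, 0.4),
    c(1, 2, 0.2), c(6, 7, 0.2))
  W <- matrix(0, 10, 10)
  W[edges[, 1:2]] <- edges[, 3]
  W <- W + t(W)
  diag(W) <- 1
  fc <- fc_matrix(W, paste0("R", 1:10))
  part <- make_partition(10, c(1, 5, 4), c("FN1", "FN2", "FN3"),
                         region_ids = paste0("R", 1:10))
  list(fc = fc, partition = part,
       stage_r = c(1, 0.9, 0.7, 0.5, 0.4, 0.2),
       cycles = list(FN2 = c(2, 3, 4, 5, 6), FN3 = c(7, 8, 10, 9)))
}
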