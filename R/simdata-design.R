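#' Default testcross trial design
#'
#' Reproduces the layout of a two-population introgression testcross trial:
#' population 1 lines each crossed to one of two elite testers, population 2
#' lines likewise except that \code{n_dual} of them are crossed to both
#' testers, plus elite check hybrids (each check line crossed to both
#' testers).  With the default sizes (68 + 70 lines, 5 dual-tester lines,
#' 3 check lines) this yields 68 + 75 = 143 experimental hybrids and 6 checks.
#' Tester assignment alternates down each population so the two testers are
#' balanced; dual-tester lines are the first \code{n_dual} ids of
#' population 2.
#'
#' @param pop1_ids,pop2_ids character vectors of line ids for the two
#'   populations.
#' @param tester_ids ids of the two testers.
#' @param check_ids ids of elite check lines (crossed to every tester).
#' @param n_dual number of population-2 lines crossed to both testers.
#' @param pop_names labels for the two populations.
#' @param environments environment ids.
#' @param replicates replicates per environment (randomized complete block).
#' @return an object of class \code{trial_design}: list with \code{hybrids}
#'   (data.frame: hybrid, line, tester, population, is_check),
#'   \code{environments} and \code{replicates}.
#' @export
default_trial_design <- function(pop1_ids, pop2_ids, tester_ids,
                                 check_ids = character(),
                                 n_dual = 5,
                                 pop_names = c("POP1", "POP2"),
                                 environments = c("CS", "BU"),
                                 replicates = 2) {
  stopifnot(length(tester_ids) == 2, replicates >= 2,
            n_dual <= length(pop2_ids))
  assign_alternating <- function(ids) tester_ids[(seq_along(ids) - 1) %% 2 + 1]

  d1 <- data.frame(line = pop1_ids, tester = assign_alternating(pop1_ids),
                   population = pop_names[1], is_check = FALSE,
                   stringsAsFactors = FALSE)
  d2 <- data.frame(line = pop2_ids, tester = assign_alternating(pop2_ids),
                   population = pop_names[2], is_check = FALSE,
                   stringsAsFactors = FALSE)
  if (n_dual > 0) {
    dual <- d2[seq_len(n_dual), ]
    dual$tester <- ifelse(dual$tester == tester_ids[1],
                          tester_ids[2], tester_ids[1])
    d2 <- rbind(d2, dual)
  }
  dc <- if (length(check_ids)) {
    data.frame(line = rep(check_ids, each = length(tester_ids)),
               tester = rep(tester_ids, length(check_ids)),
               population = "check", is_check = TRUE,
               stringsAsFactors = FALSE)
  } else NULL
  hy <- rbind(d1, d2, dc)
  hy$hybrid <- paste(hy$line, hy$tester, sep = ":")
  rownames(hy) <- NULL
  structure(list(hybrids = hy, environments = environments,
                 replicates = replicates),
            class = "trial_design")
}

#' Number of experimental (non-check) hybrids in a design
#' @param design a \code{trial_design}.
#' @export
n_experimental_hybrids <- function(design) {
  sum(!design$hybrids$is_check)
}
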