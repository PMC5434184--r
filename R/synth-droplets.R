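#' Simulate droplet digital PCR counts
#'
#' Under the standard ddPCR partition model, template molecules distribute
#' into droplets as Poisson, so a droplet is positive with probability
#' `1 - exp(-copies_per_ul * droplet_volume)`.  Positive-droplet counts for
#' the target and reference channels are drawn independently as binomials.
#'
#' @param target_copies_per_ul,reference_copies_per_ul template
#'   concentrations (copies / microliter), >= 0.
#' @param total_droplets number of droplets read.
#' @param droplet_volume droplet volume in microliters (default 0.85 nl,
#'   the nominal QX100/QX200 droplet volume).
#' @param seed integer seed.
#' @return a `droplet_counts` list: total_droplets, positives_target,
#'   positives_reference, droplet_volume.
#' @examples
#' simulate_droplets(1000, 2000, 15000, seed = 1)
#' @export
simulate_droplets <- function(target_copies_per_ul, reference_copies_per_ul,
                              total_droplets = 15000L,
                              droplet_volume = 0.00085, seed = 1L) {
  assert_scalar_number(target_copies_per_ul, "target_copies_per_ul", 0)
  assert_scalar_number(reference_copies_per_ul, "reference_copies_per_ul", 0)
  assert_scalar_number(total_droplets, "total_droplets", 1)
  assert_scalar_number(droplet_volume, "droplet_volume", 1e-12)
  set.seed(seed)
  p_t <- 1 - exp(-target_copies_per_ul * droplet_volume)
  p_r <- 1 - exp(-reference_copies_per_ul * droplet_volume)
  structure(list(
    total_droplets = as.integer(total_droplets),
    positives_target = rbinom(1L, total_droplets, p_t),
    positives_reference = rbinom(1L, total_droplets, p_r),
    droplet_volume = droplet_volume), class = "droplet_counts")
}
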