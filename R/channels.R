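#' @include AllClasses.R
NULL

#' Build the sensor/channel layout of a recording session
#'
#' Places `nSensors` MMG sensors deterministically on a spherical-cap grid
#' (a Fibonacci spiral over the cap, apex towards the pelvic floor), tags the
#' `nLower` sensors with the lowest in-plane y coordinate as `mmg_lower`
#' (the rows closest to the muscles of interest) and, among the remaining
#' sensors, the `nEdgeRef` with the largest polar angle as
#' `mmg_edge_reference` (the outer ring used as interference references).
#' Bipolar surface-EMG pairs on perineum, abdomen and thigh plus one ECG
#' lead are appended, giving 7 auxiliary channels.
#'
#' @param nSensors number of MMG sensors (array default 151).
#' @param nLower number of sensors tagged `mmg_lower` (default 20).
#' @param nEdgeRef number of sensors tagged `mmg_edge_reference` (default 12).
#' @param capRadius sphere radius of the curved array, metres.
#' @param capHalfAngle half-opening angle of the cap, radians.
#' @return data.frame of channel metadata (name, role, x, y, z, units) with
#'   `nSensors + 7` rows.
#' @examples
#' ch <- makeSensorArray(151, 20, 12)
#' table(ch$role)
#' @export
makeSensorArray <- function(nSensors = 151, nLower = 20, nEdgeRef = 12,
                            capRadius = 0.13, capHalfAngle = pi / 3) {
  if (nLower + nEdgeRef > nSensors)
    stop("nLower + nEdgeRef must not exceed nSensors")
  i <- seq_len(nSensors)
  golden <- pi * (3 - sqrt(5))
  theta <- capHalfAngle * sqrt((i - 0.5) / nSensors)  # polar angle from apex
  phi <- i * golden
  x <- capRadius * sin(theta) * cos(phi)
  y <- capRadius * sin(theta) * sin(phi)
  z <- capRadius * (cos(theta) - 1)                   # apex at origin
  role <- rep("mmg_other", nSensors)
  if (nLower > 0) role[order(y)[seq_len(nLower)]] <- "mmg_lower"
  if (nEdgeRef > 0) {
    cand <- which(role != "mmg_lower")
    role[cand[order(theta[cand], decreasing = TRUE)[seq_len(nEdgeRef)]]] <-
      "mmg_edge_reference"
  }
  mmg <- data.frame(name = sprintf("MMG%03d", i), role = role,
                    x = x, y = y, z = z, units = "fT",
                    stringsAsFactors = FALSE)
  aux <- data.frame(
    name = c("EMGper1", "EMGper2", "EMGabd1", "EMGabd2",
             "EMGthi1", "EMGthi2", "ECG1"),
    role = c("emg_perineum", "emg_perineum", "emg_abdomen", "emg_abdomen",
             "emg_thigh", "emg_thigh", "ecg"),
    x = c(0.00, 0.01, 0.00, 0.02, 0.16, 0.17, 0.05),
    y = c(-0.10, -0.11, 0.25, 0.26, -0.12, -0.13, 0.35),
    z = c(0.02, 0.02, 0.05, 0.05, 0.00, 0.00, 0.10),
    units = "uV", stringsAsFactors = FALSE)
  rbind(mmg, aux)
}

# Indices of channels whose role is in `roles`.
.roleIdx <- function(channels, roles) which(channels$role %in% roles)
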