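#' Write model parameters to a structured text file
#'
#' Versioned JSON schema holding K, the covariate names, `pi`, `B`, `W_ob`
#' and `W_tr`, so fits are portable across sessions and command-line
#' subcommands.
#'
#' @param params a [glmhmm_params()].
#' @param path output file path.
#' @param obs_covariates,tr_covariates optional column-name provenance.
#' @return `path`, invisibly.
#' @export
write_glmhmm_params <- function(params, path, obs_covariates = NULL,
                                tr_covariates = NULL) {
  obj <- list(
    schema = "glmhmm-params",
    version = 1L,
    K = params$K,
    obs_covariates = obs_covariates,
    tr_covariates = tr_covariates,
    pi = params$pi,
    W_ob = params$W_ob,
    W_tr = params$W_tr,
    B = params$B
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read model parameters from a structured text file
#'
#' @param path file written by [write_glmhmm_params()].
#' @return a [glmhmm_params()]; covariate names, when present, are attached as
#'   attributes `obs_covariates` / `tr_covariates`.
#' @export
read_glmhmm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "glmhmm-params")) {
    stop("not a glmhmm parameter file: ", path)
  }
  p <- glmhmm_params(obj$pi, as.matrix(obj$W_ob), as.matrix(obj$W_tr),
                     as.matrix(obj$B))
  attr(p, "obs_covariates") <- obj$obs_covariates
  attr(p, "tr_covariates") <- obj$tr_covariates
  p
}

#' Export per-session posteriors as a tidy table
#'
#' One row per trial: session id, trial index, the posterior state
#' probabilities and the MAP label, for downstream plotting.
#'
#' @param fit a fitted [glmhmm()] object.
#' @return data.frame.
#' @export
export_posteriors <- function(fit) {
  K <- fit$params$K
  rows <- Map(function(sid, s, b, l) {
    phi <- as.data.frame(b$phi)
    names(phi) <- paste0("phi_", seq_len(K))
    cbind(data.frame(session_id = sid, trial_index = s$trial_index), phi,
          data.frame(map_state = l))
  }, names(fit$data$sessions), fit$data$sessions, fit$posteriors,
     fit$map_labels)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
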