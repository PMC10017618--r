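# YAML/JSON run-configuration files. Sections mirror the config constructors:
#   preprocess:, augment:, loss:, network:, train:
# Unknown keys are rejected so typos fail loudly.

build_section <- function(lst, constructor, name) {
  if (is.null(lst)) return(constructor())
  known <- names(formals(constructor))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop(sprintf("unknown key(s) in '%s' section: %s", name,
                 paste(bad, collapse = ", ")))
  do.call(constructor, lst)
}

#' Read a run configuration file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON. Top-level sections `preprocess`,
#' `augment`, `loss`, `network` and `train` map onto [preprocess_config()],
#' [augment_config()], [loss_config()], [network_config()] and
#' [train_config()]; missing sections take the defaults. The `train` section
#' may not re-nest the other sections; they are attached for it.
#'
#' @param path Configuration file path.
#' @return `list(preprocess, augment, loss, network, train)` of config
#'   objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json")
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("preprocess", "augment", "loss", "network", "train"))
  if (length(bad))
    stop(sprintf("unknown top-level section(s): %s", paste(bad, collapse = ", ")))
  pre <- build_section(raw$preprocess, preprocess_config, "preprocess")
  aug <- build_section(raw$augment, augment_config, "augment")
  loss <- build_section(raw$loss, loss_config, "loss")
  net <- build_section(raw$network, network_config, "network")
  tr_lst <- raw$train
  if (!is.null(tr_lst)) {
    bad <- intersect(names(tr_lst), c("network", "loss", "augment"))
    if (length(bad))
      stop("put network/loss/augment settings in their own sections")
  }
  tr_lst <- c(tr_lst, list(network = net, loss = loss, augment = aug))
  train <- build_section(tr_lst, train_config, "train")
  list(preprocess = pre, augment = aug, loss = loss, network = net,
       train = train)
}
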