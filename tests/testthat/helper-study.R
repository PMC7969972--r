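# Study-scale pipeline fixture for the acceptance tests: the real 40x40
# Monte Carlo lookup table at the reduced 2e4 photons/node budget, the full
# 10-level factorial design, all four regression families, and the
# lookup-table inverse model on a seeded 400-row subsample of the test
# split. Built once per session (several minutes) and shared by every
# acceptance test.
study_fixture <- function() {
  memo("study", function()
    drsml::run_study(seed = 1, photons_per_node = 20000, levels = 10,
                     mclut_n = 400, n_boot = 0, verbose = FALSE))
}

study_dl_mape <- function() {
  err <- study_fixture()$report$errors
  dl <- err[err$model == "dl", ]
  stats::setNames(dl$mape, dl$parameter)[drsml::param_names()]
}
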