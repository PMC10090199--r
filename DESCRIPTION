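Package: preictal
Title: Patient-Specific Seizure Prediction from Long-Term Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested framework for patient-specific seizure prediction from
    long-term multichannel scalp EEG. Implements the full pipeline: band-pass
    and notch filtering, experimental-error and postictal discarding, pluggable
    artefact removal, 10-second windowing, extraction of 55 univariate linear
    features per channel, preictal/interictal labelling under a seizure
    occurrence period (SOP) and seizure prediction horizon (SPH), chronological
    train/test splitting, shallow feature-based and compact CNN-BiLSTM neural
    network classifiers trained as majority-vote ensembles under standard and
    chronological (periodically retrained) regimes, gap-aware firing-power
    alarm regularisation with a refractory period, and evaluation by seizure
    sensitivity, false prediction rate per hour, and surrogate chance-level
    analysis. Includes a ground-truthed synthetic EEG generator so the whole
    pipeline is exercisable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
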