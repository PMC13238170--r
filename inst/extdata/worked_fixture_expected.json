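{
  "n_cases": 12,
  "dedup_survivors": ["1012", "1021", "1032", "1041", "1051", "1061", "1071", "1081", "1091", "1101", "1111", "1121"],
  "n_target_event": 7,
  "drugx": {
    "cells": {
      "a": 4,
      "b": 2,
      "c": 3,
      "d": 3
    },
    "ror": 2,
    "ci_low": 0.194042790925719,
    "ci_high": 20.6140098321469,
    "tto_days": [30, 0, 10],
    "tto_excluded_negative": 1,
    "tto_excluded_missing": 0,
    "tto_median": 10,
    "tto_q1": 5,
    "tto_q3": 20,
    "severe": 1,
    "severe_total": 4,
    "severe_proportion": 0.25
  },
  "drugy": {
    "cells": {
      "a": 2,
      "b": 3,
      "c": 5,
      "d": 2
    },
    "ror": 0.266666666666667,
    "ci_low": 0.0235474708946482,
    "ci_high": 3.01990440626356,
    "tto_days": [12, 10],
    "severe": 1,
    "severe_total": 2,
    "severe_proportion": 0.5
  },
  "event_case_sex": {
    "F": 2,
    "M": 4,
    "unknown": 1
  }
}
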