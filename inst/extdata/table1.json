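{
  "description": "Published 2x2 contingency tables of denticle polarity in atypical cells versus the neighbour type abutting the scored membrane domain. Rows: domain abuts a tendon cell vs a non-tendon (denticulate) cell; columns: denticles pointing anteriorly vs posteriorly.",
  "tables": [
    {
      "name": "wt_row2",
      "genotype": "wild_type",
      "row_class": "atypical_row2",
      "analysis_side": "anterior",
      "row_names": ["T1 cell", "Row 2 cell"],
      "col_names": ["anteriorly", "posteriorly"],
      "counts": [[0, 52], [0, 35]],
      "n_cells": 29,
      "allocation": "none",
      "note": "All denticles point posteriorly regardless of anterior-neighbour type."
    },
    {
      "name": "wt_row4",
      "genotype": "wild_type",
      "row_class": "atypical_row4",
      "analysis_side": "posterior",
      "row_names": ["T2 cell", "Row 4 cell"],
      "col_names": ["anteriorly", "posteriorly"],
      "counts": [[110, 8], [8, 41]],
      "n_cells": 27,
      "allocation": "favour_null",
      "printed_p": 2.2e-16,
      "p_is_upper_bound": true,
      "note": "8 of the 8 tendon/posteriorly and 6 of the 8 non-tendon/anteriorly denticles arose from ambiguously placed predenticles, allocated to the classes favouring the null hypothesis."
    },
    {
      "name": "mut_row2",
      "genotype": "ds_ft_null",
      "row_class": "atypical_row2",
      "analysis_side": "anterior",
      "row_names": ["T1 cell", "Row 2 cell"],
      "col_names": ["anteriorly", "posteriorly"],
      "counts": [[16, 21], [14, 13]],
      "n_cells": 23,
      "allocation": "none",
      "printed_p": 0.6135
    },
    {
      "name": "mut_row4",
      "genotype": "ds_ft_null",
      "row_class": "atypical_row4",
      "analysis_side": "posterior",
      "row_names": ["T2 cell", "Row 4 cell"],
      "col_names": ["anteriorly", "posteriorly"],
      "counts": [[54, 37], [24, 20]],
      "n_cells": 24,
      "allocation": "disfavour_null",
      "printed_p": 0.7104,
      "note": "1 of the 54 tendon/anteriorly and 1 of the 20 non-tendon/posteriorly denticles arose from ambiguously placed predenticles, allocated to the classes disfavouring the null hypothesis."
    }
  ]
}
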