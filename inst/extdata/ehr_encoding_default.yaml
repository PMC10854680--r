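# Default ordinal-encoding thresholds for EHR features.
#
# SYNTHETIC DEFAULTS: these cut points are clinically plausible values
# assembled from common critical-care reference ranges; they are NOT a
# canonical published encoding.  Supply your own file with the same
# structure to use site-specific thresholds.
#
# Labs: three strictly ordered thresholds per analyte map a raw value to
# severity 1..4 (0 = nothing logged).  direction "high" means severity
# grows with the value; "low" means severity grows as the value falls.
labs:
  creatinine:     {direction: high, thresholds: [1.2, 2.0, 3.5], units: mg/dL}
  glucose:        {direction: high, thresholds: [140, 180, 250], units: mg/dL}
  hematocrit:     {direction: low,  thresholds: [36, 30, 24],    units: "%"}
  hemoglobin:     {direction: low,  thresholds: [12, 10, 8],     units: g/dL}
  inr:            {direction: high, thresholds: [1.2, 1.5, 2.5], units: ratio}
  lactate:        {direction: high, thresholds: [2.0, 4.0, 8.0], units: mmol/L}
  platelet_count: {direction: low,  thresholds: [150, 100, 50],  units: 1e3/uL}
  potassium:      {direction: high, thresholds: [4.5, 5.5, 6.5], units: mmol/L}
  sodium:         {direction: high, thresholds: [145, 150, 155], units: mmol/L}
  wbc:            {direction: high, thresholds: [12, 15, 25],    units: 1e3/uL}
# Cardiovascular infusions: two strictly increasing dose thresholds map a
# logged dose to severity 1..3 (0 = not running).
infusions:
  dobutamine:     {thresholds: [5, 10],      units: ug/kg/min}
  dopamine:       {thresholds: [5, 15],      units: ug/kg/min}
  epinephrine:    {thresholds: [0.05, 0.2],  units: ug/kg/min}
  isoproterenol:  {thresholds: [2, 5],       units: ug/min}
  milrinone:      {thresholds: [0.25, 0.5],  units: ug/kg/min}
  norepinephrine: {thresholds: [0.05, 0.3],  units: ug/kg/min}
  vasopressin:    {thresholds: [0.02, 0.04], units: U/min}
# Population defaults used when a numeric vital/urine value is missing at
# every lookback (no value to carry forward).
vital_defaults:
  temperature: 37.0
  spo2: 97.0
  heart_rate: 80.0
  mean_arterial_pressure: 85.0
  respiratory_rate: 16.0
  urine_output: 60.0
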