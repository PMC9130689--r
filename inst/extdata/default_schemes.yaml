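# Shipped calibration configuration: one entry per factor with its raw-table
# source column, the two cut-points (low <= c1 < medium <= c2 < high) and the
# observed raw range used by the synthetic generator.
EDU:       {column: pct_college,         cuts: [20, 40.1],      range: [4.5, 85.6]}
ICEBLACK:  {column: ice_black,           cuts: [-0.37, 0.47],   range: [-1, 1]}
ICEINC:    {column: ice_income,          cuts: [-0.23, 0.07],   range: [-1, 1]}
UNINS:     {column: pct_uninsured,       cuts: [6.5, 9.7],      range: [2.7, 13.8]}
LEP:       {column: pct_limited_english, cuts: [2.2, 4.7],      range: [0.4, 25.1]}
TRANSIT:   {column: pct_public_transit,  cuts: [21.4, 29.5],    range: [9.2, 45.3]}
SERVICE:   {column: pct_service,         cuts: [7.9, 9.8],      range: [1.9, 16.9]}
OVERCROWD: {column: pct_overcrowded,     cuts: [1.7, 2.4],      range: [0, 6.1]}
VAX_MAR:   {column: vax_rate_mar,        cuts: [1500, 2000],    range: [0, 3000]}
VAX_APR:   {column: vax_rate_apr,        cuts: [2500, 3400],    range: [0, 5100]}
VAX_MAY:   {column: vax_rate_may,        cuts: [3400, 4500],    range: [0, 6750]}
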