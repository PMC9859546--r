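# Synthetic lumbar ultimate-compressive-strength (UCS) coefficients.
# Constructed, not fitted to a specific dataset: the values sit in the range
# of published lumbar strength regressions (baseline a few kN, roughly
# 0.5 kN loss per decade of age, higher strength in males, strength scaling
# with endplate area which grows with BMI).
#   UCS [N] = (c0 + c_sex*[male] - c_age*age/10) * clip(b0 + b1*BMI, 0.5, 1.5) * 1000
# b0/b1 chosen so the area factor is 1.0 at BMI 25.
c0: 7.7      # kN, baseline (female, extrapolated age 0)
c_age: 0.5   # kN per decade of age
c_sex: 1.2   # kN, additive for male subjects
b0: 0.85     # area-factor intercept
b1: 0.006    # area-factor slope per BMI unit
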