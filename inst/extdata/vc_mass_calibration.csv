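# Empirical calibration relating the volume-of-correlation ratio
# QR = Vc^2 / Rg (units A^3) to molecular mass in Da: M = (QR / coefficient)
# ^ exponent. Constants from Rambo & Tainer (2013), Nature 496, 477-481
# (protein and RNA calibrations).
class,coefficient,exponent
protein,0.1231,1.000
nucleic_acid,0.00934,0.808
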