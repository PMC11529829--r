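# linear attenuation coefficients for czt (cm^-1)
# generated by data-raw/make_material_tables.R (parametrized model:
#  Klein-Nishina Compton + anchored semi-empirical photoelectric/Rayleigh)
# energy_keV mu_photo mu_compton mu_rayleigh
10.0000 5.78187174e+03 9.30355412e-01 2.08896800e+01
11.4075 3.90542859e+03 9.25568204e-01 1.60528014e+01
13.0131 2.63894642e+03 9.20185903e-01 1.23358833e+01
14.8448 1.78387846e+03 9.14145743e-01 9.47944881e+00
16.9342 1.20646985e+03 9.07382667e-01 7.28454479e+00
19.3177 8.16395498e+02 8.99827920e-01 5.59784608e+00
22.0367 5.52774708e+02 8.91411513e-01 4.30168563e+00
25.1384 3.74537017e+02 8.82063314e-01 3.30564736e+00
28.6766 2.53969370e+02 8.71714851e-01 2.54025006e+00
32.7129 1.72362676e+02 8.60300703e-01 1.95206239e+00
37.3173 1.17093298e+02 8.47762403e-01 1.50006943e+00
42.5697 7.96345027e+01 8.34050473e-01 1.15273800e+00
48.5615 5.42253391e+01 8.19127067e-01 8.85824323e-01
55.3966 3.69744767e+01 8.02970732e-01 6.80715385e-01
63.1937 2.52503732e+01 7.85578285e-01 5.23099397e-01
72.0883 1.72731166e+01 7.66967859e-01 4.01977939e-01
82.2349 1.18382884e+01 7.47181411e-01 3.08901097e-01
93.8095 8.13034306e+00 7.26286204e-01 2.37376731e-01
107.0134 5.59646941e+00 7.04373400e-01 1.82412864e-01
122.0756 3.86188825e+00 6.81558479e-01 1.40176126e-01
139.2579 2.67212544e+00 6.57976288e-01 1.07718948e-01
158.8587 1.85430393e+00 6.33777743e-01 8.27770183e-02
181.2183 1.29082584e+00 6.09123825e-01 6.36103351e-02
206.7250 9.01591487e-01 5.84178877e-01 4.88816420e-02
235.8218 6.31969134e-01 5.59104081e-01 3.75633128e-02
269.0140 4.44639951e-01 5.34051416e-01 2.88656953e-02
306.8781 3.14066504e-01 5.09158517e-01 2.21819639e-02
350.0717 2.22740421e-01 4.84545260e-01 1.70458154e-02
399.3447 1.58632739e-01 4.60312117e-01 1.30989335e-02
455.5530 1.13459188e-01 4.36539837e-01 1.00659314e-02
519.6727 8.15007857e-02 4.13291364e-01 7.73520774e-03
592.8174 5.87983500e-02 3.90614318e-01 5.94415195e-03
676.2573 4.26029508e-02 3.68544345e-01 4.56780815e-03
771.4414 3.09998387e-02 3.47108426e-01 3.51015184e-03
880.0228 2.26507823e-02 3.26327905e-01 2.69739122e-03
1003.8872 1.66171399e-02 3.06220982e-01 2.07282173e-03
1145.1857 1.22380440e-02 2.86804377e-01 1.59286861e-03
1306.3722 9.04635905e-03 2.68094223e-01 1.22404653e-03
1490.2459 6.71053860e-03 2.50106309e-01 9.40623698e-04
1700.0000 4.99427795e-03 2.32855754e-01 7.22826298e-04
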