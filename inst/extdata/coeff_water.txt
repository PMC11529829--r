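# linear attenuation coefficients for water (cm^-1)
# generated by data-raw/make_material_tables.R (parametrized model:
#  Klein-Nishina Compton + anchored semi-empirical photoelectric/Rayleigh)
# energy_keV mu_photo mu_compton mu_rayleigh
10.0000 2.36616821e+00 2.14099513e-01 1.90000000e-01
11.4075 1.59825423e+00 2.12997849e-01 1.46006653e-01
13.0131 1.07996016e+00 2.11759239e-01 1.12199796e-01
14.8448 7.30032883e-01 2.10369237e-01 8.62193807e-02
16.9342 4.93734681e-01 2.08812874e-01 6.62558503e-02
19.3177 3.34100990e-01 2.07074326e-01 5.09146504e-02
22.0367 2.26217045e-01 2.05137487e-01 3.91255524e-02
25.1384 1.53275206e-01 2.02986217e-01 3.00661857e-02
28.6766 1.03934206e-01 2.00604761e-01 2.31045909e-02
32.7129 7.05375531e-02 1.97978062e-01 1.77547887e-02
37.3173 4.79191602e-02 1.95092666e-01 1.36437318e-02
42.5697 3.25895552e-02 1.91937186e-01 1.04846134e-02
48.5615 2.21911310e-02 1.88502914e-01 8.05692674e-03
55.3966 1.51314030e-02 1.84784912e-01 6.19137886e-03
63.1937 1.03334410e-02 1.80782447e-01 4.75779836e-03
72.0883 7.06883536e-03 1.76499694e-01 3.65615023e-03
82.2349 4.84469095e-03 1.71946306e-01 2.80957910e-03
93.8095 3.32725458e-03 1.67137763e-01 2.15903637e-03
107.0134 2.29029432e-03 1.62095045e-01 1.65911800e-03
122.0756 1.58043582e-03 1.56844725e-01 1.27495796e-03
139.2579 1.09353831e-03 1.51417836e-01 9.79746944e-04
158.8587 7.58853744e-04 1.45849107e-01 7.52890110e-04
181.2183 5.28256454e-04 1.40175585e-01 5.78561455e-04
206.7250 3.68966523e-04 1.34435090e-01 4.44598097e-04
235.8218 2.58626503e-04 1.28664712e-01 3.41653364e-04
269.0140 1.81964070e-04 1.22899428e-01 2.62545051e-04
306.8781 1.28528305e-04 1.17170910e-01 2.01753839e-04
350.0717 9.11540977e-05 1.11506746e-01 1.55038513e-04
399.3447 6.49187254e-05 1.05930055e-01 1.19140043e-04
455.5530 4.64319402e-05 1.00459422e-01 9.15536744e-05
519.6727 3.33533113e-05 9.51093298e-02 7.03548102e-05
592.8174 2.40625861e-05 8.98907387e-02 5.40644409e-05
676.2573 1.74347948e-05 8.48118513e-02 4.15460432e-05
771.4414 1.26863473e-05 7.98788764e-02 3.19262358e-05
880.0228 9.26958663e-06 7.50967261e-02 2.45338527e-05
1003.8872 6.80038400e-06 7.04695887e-02 1.88531432e-05
1145.1857 5.00828659e-06 6.60013115e-02 1.44877775e-05
1306.3722 3.70212418e-06 6.16956077e-02 1.11331931e-05
1490.2459 2.74621503e-06 5.75561105e-02 8.55534898e-06
1700.0000 2.04385400e-06 5.35862993e-02 6.57439446e-06
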