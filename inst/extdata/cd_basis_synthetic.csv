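# Synthetic schematic reference CD basis spectra (mean residue ellipticity,
# deg*cm^2/dmol) for pure alpha-helix, beta-strand and random-coil states.
# Shaped after the classic poly-amino-acid reference spectra (helix: +193 nm
# band, double minima at 208/222 nm; strand: +196/-217 nm; coil: -198 nm).
# These are smooth synthetic stand-ins, not digitised experimental data;
# swap in a measured basis via the basis argument of synthesize_cd_spectrum().
wavelength,helix,beta,coil
190,74363,11770,-11322
191,75810,15976,-15380
192,74123,20512,-20053
193,69449,24910,-25098
194,62253,28614,-30151
195,53219,31088,-34766
196,43115,31940,-38476
197,32665,31023,-40866
198,22443,28472,-41651
199,12833,24665,-40729
200,4025,20123,-38201
201,-3931,15386,-34350
202,-11064,10902,-29589
203,-17415,6959,-24385
204,-22994,3671,-19184
205,-27766,1007,-14347
206,-31662,-1154,-10121
207,-34611,-2963,-6626
208,-36581,-4564,-3875
209,-37608,-6060,-1803
210,-37811,-7507,-300
211,-37386,-8915,758
212,-36576,-10256,1488
213,-35639,-11480,1987
214,-34800,-12524,2330
215,-34220,-13324,2569
216,-33978,-13828,2738
217,-34061,-14000,2856
218,-34381,-13828,2935
219,-34797,-13325,2982
220,-35141,-12528,2998
221,-35248,-11491,2986
222,-34981,-10282,2947
223,-34248,-8977,2882
224,-33005,-7646,2794
225,-31262,-6353,2685
226,-29074,-5150,2556
227,-26531,-4073,2413
228,-23747,-3143,2257
229,-20842,-2366,2093
230,-17934,-1738,1924
231,-15128,-1245,1752
232,-12509,-870,1582
233,-10139,-594,1416
234,-8056,-395,1255
235,-6274,-256,1104
236,-4789,-162,962
237,-3584,-100,830
238,-2628,-60,711
239,-1890,-36,603
240,-1332,-20,507
241,-920,-11,423
242,-623,-6,349
243,-413,-3,286
244,-269,-2,232
245,-171,-1,187
246,-107,0,149
247,-66,0,117
248,-39,0,92
249,-23,0,71
250,-13,0,55
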