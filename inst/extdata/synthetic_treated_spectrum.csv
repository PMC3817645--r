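wavelength_nm,absorbance
200,5.379462978223399e-4
202,8.012299896006897e-4
204,0.001178836120341218
206,0.0017132784039558013
208,0.002459693969560145
210,0.003488295531939609
212,0.004886805295424469
214,0.006762650915572461
216,0.009244635266033991
218,0.012483728044505938
220,0.01665257857097221
222,0.021943327522373515
224,0.02856331356101404
226,0.03672834059611814
228,0.04665330134704328
230,0.05854014598342916
232,0.07256343615099034
234,0.08885402047658927
236,0.10748168350605593
238,0.12843792268157006
240,0.15162025763943188
242,0.17681963085080796
244,0.20371247997116068
246,0.23185892157346297
248,0.26070817048386075
250,0.2896118365914965
252,0.3178451225377443
254,0.3446352438541226
256,0.36919567818905263
258,0.3907642023170562
260,0.4086421744174869
262,0.4222322329902103
264,0.4310715593425518
266,0.43485810485810483
268,0.43346770080345165
270,0.42696069823243815
272,0.41557765274003267
274,0.39972448041655184
276,0.3799483695457315
278,0.3569064476220322
280,0.33132970490896885
282,0.3039849216466803
284,0.2756373256373257
286,0.24701644098843104
288,0.21878712424132588
290,0.1915271860566547
292,0.1657123384907897
294,0.1417085615207747
296,0.1197714096220125
298,0.10005132547300925
300,0.08260371958312075
302,0.06740241871251985
304,0.05435507219726246
306,0.04331921053823143
308,0.034117843672476174
310,0.026553733015118024
312,0.020421738793196826
314,0.015518904205108923
316,0.011652169052970462
318,0.008643793751359907
320,0.006334713339190786
322,0.004586129917552678
324,0.003279695229553026
326,0.0023166404979293575
328,0.0016161873664020372
330,0.00111353134700171
332,7.576363037123645e-4
334,5.090225286574433e-4
336,3.3767745892024934e-4
338,2.211707917629133e-4
340,1.4301676877825968e-4
342,9.129641699622443e-5
344,5.7531221324577326e-5
346,3.578603686695971e-5
348,2.1971642232127485e-5
350,1.3314684729375456e-5
352,7.963448258570031e-6
354,4.700648492798654e-6
356,2.7383389981741202e-6
358,1.574265783356916e-6
360,8.93143107243662e-7
362,5.000450390056684e-7
364,2.762723437133804e-7
366,1.5062715996190423e-7
368,8.104129248068081e-8
370,4.302773391796406e-8
372,2.254414232362163e-8
374,1.1656505987960012e-8
376,5.947863520047902e-9
378,2.9951749345933012e-9
380,1.4885546137881876e-9
382,7.301357191490401e-10
384,3.5347241270520683e-10
386,1.6890377457707077e-10
388,7.966649664079729e-11
390,3.709257457212667e-11
392,1.704892888416625e-11
394,7.736268098702381e-12
396,3.465907353098318e-12
398,1.5331380779075576e-12
400,6.696583041112033e-13
402,2.888433754514372e-13
404,1.2303784201555149e-13
406,5.176215514532625e-14
408,2.1508668740708288e-14
410,8.8281995389643292e-15
412,3.579459954221348e-15
414,1.433765497430464e-15
416,5.673896125553642e-16
418,2.2184686837240368e-16
420,8.570739918321489e-17
422,3.271892502841388e-17
424,1.234286619976445e-17
426,4.6013758646536456e-18
428,1.6952361219656076e-18
430,6.172444471450504e-19
432,2.2211605589344954e-19
434,7.899639749625582e-20
436,2.7768061852507354e-20
438,9.647145164264942e-21
440,3.3125983383734082e-21
442,1.1242298101373782e-21
444,3.7709904171871915e-22
446,1.2501601536183784e-22
448,4.096189641820874e-23
450,1.326452002070307e-23
452,4.2451382377418234e-24
454,1.3426775186341676e-24
456,4.19682823574521e-25
458,1.2963722571269718e-25
460,3.957185446931134e-26
462,1.1936585282215117e-26
464,3.557948633979598e-27
466,1.047934260778046e-27
468,3.0498068855968183e-28
470,8.77008952397284e-29
472,2.491833027349929e-29
474,6.995316549070483e-30
476,1.9402609051469516e-30
478,5.317023351801432e-31
480,1.4395428124529014e-31
482,3.8505314073204416e-32
484,1.0175362263460321e-32
486,2.6564756521072477e-33
488,6.851453681459651e-34
490,1.7457226498660868e-34
492,4.3941878200740447e-35
494,1.0926687607696532e-35
496,2.6841150115582705e-36
498,6.51347810028969e-37
500,1.5614244668714013e-37
502,3.697621796950932e-38
504,8.649979975892938e-39
506,1.998926085371592e-39
508,4.56315862111621e-40
510,1.0290109751495275e-40
512,2.2922325976795714e-41
514,5.044061938539969e-42
516,1.0964382178529892e-42
518,2.3543394038133476e-43
520,4.993837218237507e-44
522,1.0463559778540678e-44
524,2.1657272726048978e-45
526,4.4279921551706885e-46
528,8.943104534774567e-47
530,1.7842176704526655e-47
532,3.5162938411245015e-48
534,6.845419278466872e-49
536,1.3164135082938639e-49
538,2.5007013858278814e-50
540,4.692544932243775e-51
542,8.698253090140713e-52
544,1.5926947530271966e-52
546,2.8807786995376844e-53
548,5.147116832763619e-54
550,9.084371579301734e-55
552,1.5838077012957347e-55
554,2.7276376551633814e-56
556,4.6403158881548176e-57
558,7.798032431309354e-58
560,1.2944912959338735e-58
562,2.12270589614265e-59
564,3.438405572151516e-60
566,5.5017512894461745e-61
568,8.69603693935922e-62
570,1.3577454716847507e-62
572,2.0940734542549482e-63
574,3.190377091426234e-64
576,4.801408764345433e-65
578,7.137923641141809e-66
580,1.0482181307434499e-66
582,1.5205754993694663e-67
584,2.178917869458362e-68
586,3.084255037806016e-69
588,4.3125709653783534e-70
590,5.956604645111113e-71
592,8.127141963854604e-72
594,1.0953513932574708e-72
596,1.458295825530315e-73
598,1.9178487274662585e-74
600,2.4914926666444625e-75
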