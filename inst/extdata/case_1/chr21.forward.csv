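pos,c,noc,mc,hmc
1,54,1,2,0
2,40,0,4,0
3,49,0,1,0
4,49,0,3,0
5,45,1,6,0
6,49,0,2,0
7,32,3,1,0
8,33,1,14,0
9,47,1,0,0
10,49,0,8,0
11,52,0,2,0
12,41,1,11,0
13,49,1,1,0
14,47,0,5,0
15,46,0,4,0
16,45,0,15,0
17,37,1,13,0
18,46,0,1,0
19,54,1,3,0
20,41,1,7,0
21,50,0,2,0
22,53,2,4,0
23,29,0,7,0
24,41,1,2,0
26,36,0,7,0
27,54,1,1,0
28,55,1,1,0
29,47,0,2,0
30,47,0,8,0
31,55,0,4,0
32,60,1,7,0
33,41,0,1,0
34,47,1,11,0
35,40,0,5,0
36,35,0,7,0
37,35,0,19,0
38,57,1,0,0
39,36,0,13,0
40,54,0,0,0
42,57,1,0,0
43,44,0,1,0
44,48,1,1,0
46,52,0,1,0
48,37,0,11,0
49,45,0,9,0
50,37,0,4,0
51,42,0,0,0
52,53,0,0,0
54,49,0,0,0
55,41,0,10,0
56,57,1,0,0
57,41,0,3,0
58,51,1,5,0
59,41,1,3,0
60,49,0,5,0
61,36,0,2,0
62,51,2,2,0
63,48,0,3,0
64,51,1,1,0
65,39,0,0,0
66,48,0,9,0
67,36,0,6,0
68,38,0,2,0
69,35,1,4,0
70,47,0,4,0
71,51,0,0,0
72,38,0,2,0
73,57,0,0,0
74,41,1,2,0
75,40,1,14,0
77,50,0,0,0
79,35,2,9,0
81,53,2,0,0
83,57,0,0,0
84,29,4,7,0
86,45,2,7,0
87,46,0,2,0
88,40,1,1,0
89,37,0,4,0
90,53,0,7,0
91,37,0,5,0
92,45,1,1,0
93,37,0,5,0
94,53,0,6,0
95,20,0,36,0
96,15,1,41,0
97,23,0,30,0
98,25,1,30,0
99,30,0,10,0
100,17,0,36,0
101,21,1,22,0
102,31,0,32,0
103,40,0,4,0
104,38,1,11,0
105,33,1,24,0
106,40,0,17,0
107,23,0,29,0
108,36,0,13,0
109,42,1,14,0
110,34,1,17,0
111,36,0,24,0
112,33,0,7,0
113,34,0,38,0
114,31,2,20,0
115,37,1,13,0
116,27,0,20,0
117,43,0,21,0
118,25,0,25,0
119,19,0,37,0
120,5,1,29,0
121,21,0,23,0
122,14,0,23,0
123,28,1,18,0
124,36,0,18,0
125,21,0,25,0
126,23,1,23,0
127,26,1,16,0
128,35,0,11,0
129,12,0,40,0
130,31,0,7,0
131,11,0,40,0
132,21,1,24,0
133,20,0,30,0
134,15,0,46,0
135,31,1,24,0
136,17,0,37,0
137,24,1,33,0
138,12,0,40,0
140,30,0,42,0
141,28,0,24,0
142,24,1,33,0
143,19,1,37,0
144,34,1,21,0
145,25,0,32,0
146,26,1,26,0
148,22,0,14,0
149,38,1,19,0
150,26,0,34,0
151,38,0,7,0
152,33,0,36,0
153,45,3,21,0
154,16,2,42,0
155,18,1,30,0
156,28,1,15,0
158,6,0,41,0
159,43,0,14,0
160,23,1,32,0
161,42,1,18,0
162,11,0,36,0
163,31,0,22,0
164,11,0,29,0
165,24,0,29,0
166,12,0,34,0
167,19,0,33,0
168,23,0,24,0
169,31,0,18,0
170,24,0,23,0
171,22,0,28,0
174,17,0,28,0
175,26,0,29,0
176,12,0,30,0
178,39,0,22,0
179,26,0,19,0
180,28,0,25,0
181,39,0,12,0
182,26,0,24,0
183,26,0,19,0
184,28,0,19,0
185,19,0,30,0
186,30,1,13,0
187,38,0,7,0
189,44,0,3,0
190,43,0,10,0
191,43,0,2,0
192,38,0,18,0
193,44,0,1,0
194,52,0,7,0
195,46,0,6,0
196,60,0,8,0
197,45,0,1,0
199,52,0,1,0
200,56,1,2,0
201,41,0,6,0
203,51,0,2,0
204,25,1,16,0
205,53,1,2,0
206,49,0,1,0
207,35,1,4,0
208,41,1,3,0
210,43,1,1,0
211,52,1,1,0
212,46,0,2,0
213,44,2,1,0
214,45,0,6,0
215,66,2,1,0
216,51,0,0,0
217,49,0,0,0
218,31,0,7,0
219,57,2,0,0
220,41,1,1,0
221,42,0,9,0
222,50,1,1,0
223,53,1,0,0
224,34,0,6,0
225,49,1,1,0
226,34,0,17,0
227,63,1,1,0
228,40,0,5,0
229,42,2,13,0
230,51,1,5,0
232,43,1,4,0
233,31,0,20,0
234,47,1,4,0
236,55,0,0,0
238,44,1,10,0
239,32,0,16,0
240,48,0,8,0
241,53,1,1,0
242,54,2,0,0
243,55,0,14,0
244,50,1,1,0
245,46,0,0,0
246,37,0,4,0
247,44,1,0,0
248,47,0,4,0
249,38,0,0,0
250,36,0,16,0
251,44,0,0,0
253,50,0,2,0
254,37,0,4,0
255,35,0,5,0
256,34,0,15,0
258,46,0,0,0
259,49,0,1,0
260,53,0,0,0
261,46,2,0,0
262,27,0,24,0
263,48,1,0,0
264,29,2,8,0
265,55,1,0,0
266,53,2,1,0
267,41,2,3,0
268,46,0,0,0
269,47,0,0,0
270,55,1,3,0
271,49,0,2,0
272,43,1,2,0
273,25,1,26,0
274,56,0,0,0
275,43,1,2,0
276,36,0,6,0
277,51,0,2,0
278,53,3,6,0
279,48,0,0,0
280,39,0,14,0
281,53,0,0,0
282,44,1,2,0
283,64,1,0,0
284,34,1,5,0
285,49,1,1,0
286,38,1,2,0
287,48,0,6,0
288,35,0,14,0
289,41,2,14,0
290,39,0,4,0
291,41,1,13,0
292,40,1,3,0
293,51,0,1,0
294,51,0,0,0
295,53,2,2,0
296,55,0,2,0
297,47,0,1,0
298,62,0,0,0
299,46,2,2,0
300,32,1,15,0
301,37,0,14,0
302,48,0,2,0
303,30,0,13,0
304,19,1,39,0
305,25,0,26,0
306,36,0,31,0
307,30,0,11,0
308,42,1,9,0
309,26,1,18,0
310,31,0,12,0
311,36,0,19,0
312,9,0,34,0
313,30,0,14,0
314,32,0,21,0
316,42,0,15,0
317,28,0,15,0
319,16,0,29,0
320,29,2,16,0
321,24,0,29,0
322,18,0,22,0
323,30,0,13,0
324,23,0,30,0
325,29,1,34,0
326,9,0,36,0
327,13,0,29,0
328,23,1,27,0
329,8,0,45,0
330,17,0,22,0
331,21,0,24,0
332,18,1,35,0
333,40,0,12,0
334,20,0,24,0
335,29,1,7,0
336,44,0,10,0
337,27,1,17,0
338,15,0,31,0
339,38,2,21,0
340,22,0,22,0
341,31,0,27,0
342,11,1,37,0
343,25,2,22,0
344,27,0,26,0
345,33,0,17,0
347,46,0,6,0
348,42,0,12,0
349,21,1,13,0
350,13,0,25,0
352,20,0,31,0
353,28,0,22,0
354,28,0,34,0
355,21,0,28,0
356,38,0,12,0
358,31,0,18,0
359,36,3,30,0
360,22,2,23,0
361,15,0,42,0
363,20,0,39,0
365,25,0,20,0
366,22,0,32,0
368,12,1,45,0
369,16,0,21,0
370,33,0,25,0
371,11,2,21,0
372,33,0,16,0
373,34,0,14,0
374,27,0,27,0
375,15,1,41,0
377,26,0,35,0
378,31,0,23,0
380,20,1,21,0
381,31,0,16,0
382,24,1,23,0
383,19,0,20,0
384,26,0,28,0
386,16,0,31,0
387,23,0,39,0
388,24,1,17,0
389,23,0,25,0
390,29,0,16,0
391,17,2,35,0
392,43,1,23,0
393,33,0,17,0
394,15,0,24,0
395,17,1,32,0
396,9,0,39,0
397,8,2,30,0
398,17,0,24,0
399,54,1,2,0
400,31,0,23,0
401,33,0,17,0
402,46,1,1,0
403,54,1,0,0
404,63,0,3,0
406,43,0,10,0
407,39,1,10,0
408,49,1,1,0
409,37,0,2,0
410,53,2,2,0
411,54,1,6,0
412,40,1,0,0
414,42,1,7,0
415,45,0,0,0
416,55,1,6,0
417,40,1,4,0
418,53,1,2,0
419,52,0,4,0
420,39,1,3,0
421,41,0,7,0
422,41,0,1,0
423,38,2,3,0
424,32,1,10,0
425,61,1,2,0
426,53,2,4,0
427,38,0,10,0
428,40,1,0,0
429,42,0,0,0
430,56,0,8,0
431,43,1,9,0
432,35,0,3,0
434,38,0,6,0
435,39,0,3,0
436,44,0,0,0
437,54,0,3,0
438,49,1,2,0
439,49,0,1,0
440,45,0,16,0
441,34,0,12,0
442,49,0,0,0
443,42,2,8,0
444,42,0,3,0
445,37,1,1,0
446,38,1,3,0
447,36,1,3,0
448,53,3,4,0
449,41,0,10,0
450,52,1,3,0
451,50,0,4,0
452,49,1,1,0
453,40,1,2,0
454,50,0,1,0
455,32,0,15,0
456,53,1,4,0
457,61,1,2,0
458,43,1,0,0
459,29,0,19,0
460,48,1,0,0
461,56,1,1,0
462,38,2,8,0
463,61,0,0,0
464,52,1,0,0
465,44,0,2,0
466,34,0,4,0
467,42,0,9,0
468,38,0,16,0
469,50,0,0,0
470,46,0,2,0
471,34,2,14,0
472,46,0,1,0
474,33,0,6,0
475,41,0,2,0
476,34,1,1,0
477,49,0,4,0
478,44,1,3,0
479,60,0,6,0
480,34,0,15,0
481,63,1,2,0
482,49,0,2,0
483,46,0,2,0
484,53,0,0,0
485,41,0,12,0
486,38,1,2,0
487,57,1,4,0
488,45,0,5,0
489,47,0,9,0
490,52,0,1,0
491,57,0,3,0
492,42,0,2,0
493,49,1,3,0
495,37,1,8,0
496,38,0,1,0
497,54,0,2,0
498,35,1,3,0
499,53,1,3,0
500,51,1,3,0
501,60,1,0,0
502,47,0,3,0
504,49,1,2,0
505,54,0,0,0
506,42,0,2,0
507,43,1,1,0
508,39,0,4,0
510,46,2,6,0
511,49,0,4,0
512,47,0,2,0
513,63,1,2,0
514,57,0,0,0
515,40,0,0,0
517,45,0,0,0
518,42,1,5,0
519,32,0,11,0
520,43,1,3,0
521,62,0,2,0
522,43,1,13,0
523,39,0,11,0
524,44,0,5,0
525,36,0,4,0
526,34,0,6,0
527,48,0,0,0
528,40,0,17,0
530,52,1,3,0
531,40,0,2,0
532,55,0,4,0
533,39,0,4,0
534,56,0,0,0
535,30,0,16,0
536,48,1,1,0
537,48,0,6,0
538,32,1,25,0
539,32,0,13,0
540,51,0,1,0
541,52,1,0,0
542,33,0,17,0
543,56,0,3,0
544,27,1,10,0
545,53,1,4,0
546,45,0,0,0
547,50,0,1,0
548,40,0,3,0
549,53,1,6,0
550,45,0,12,0
551,40,0,5,0
553,48,0,1,0
554,30,0,10,0
555,48,0,1,0
556,44,0,15,0
558,55,0,2,0
559,48,0,8,0
560,56,1,2,0
561,45,2,5,0
562,57,0,2,0
563,36,0,8,0
564,42,0,3,0
565,29,0,21,0
566,47,2,9,0
567,46,0,9,0
568,43,0,4,0
569,33,1,18,0
570,46,1,2,0
572,59,1,1,0
573,36,0,0,0
574,50,0,2,0
575,34,2,5,0
576,29,3,16,0
577,36,0,13,0
578,44,0,9,0
580,42,2,2,0
581,43,1,1,0
582,49,1,4,0
583,43,0,5,0
584,24,0,8,0
585,49,1,7,0
586,46,0,5,0
587,49,0,5,0
588,38,0,2,0
589,57,0,5,0
590,64,0,0,0
591,38,2,14,0
593,38,0,10,0
595,43,1,1,0
596,33,0,9,0
597,38,1,3,0
598,43,0,0,0
599,35,1,4,0
600,42,2,2,0
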