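pos,c,noc,mc,hmc
1,45,1,0,0
2,25,0,23,0
3,56,1,1,0
4,47,1,4,0
5,48,1,0,0
6,37,0,21,0
7,43,1,0,0
8,33,2,10,0
9,49,1,2,0
10,38,0,0,0
11,43,2,16,0
12,52,0,3,0
13,47,2,1,0
14,43,0,4,0
15,56,0,0,0
16,41,0,7,0
17,51,1,3,0
18,40,0,1,0
19,54,1,3,0
20,50,1,1,0
21,47,0,3,0
22,52,0,8,0
23,37,1,8,0
24,65,0,3,0
26,47,2,5,0
27,48,1,1,0
28,58,1,1,0
29,37,1,14,0
30,55,0,1,0
31,49,0,7,0
32,58,0,3,0
33,35,1,2,0
34,57,1,0,0
35,31,0,19,0
36,52,0,1,0
37,35,0,14,0
38,44,0,0,0
39,48,1,1,0
40,38,1,11,0
42,34,1,4,0
43,59,0,5,0
44,45,3,2,0
46,38,1,5,0
48,57,0,1,0
49,47,0,4,0
50,34,0,11,0
51,50,0,0,0
52,45,1,15,0
54,43,1,7,0
55,28,0,18,0
56,46,1,1,0
57,49,0,0,0
58,36,2,4,0
59,42,0,1,0
60,46,1,0,0
61,55,3,0,0
62,37,0,12,0
63,33,0,5,0
64,30,1,11,0
65,45,0,0,0
66,55,1,0,0
67,39,1,3,0
68,45,3,20,0
69,55,0,1,0
70,57,1,2,0
71,47,1,5,0
72,32,0,4,0
73,64,0,1,0
74,41,0,1,0
75,47,1,1,0
77,43,0,0,0
79,45,0,4,0
81,57,1,2,0
83,58,1,0,0
84,35,1,15,0
86,53,0,3,0
87,44,0,5,0
88,53,1,3,0
89,45,1,4,0
90,59,1,2,0
91,34,0,3,0
92,33,0,10,0
93,57,1,0,0
94,62,1,0,0
95,38,0,19,0
96,43,0,21,0
97,32,0,22,0
98,8,2,28,0
99,26,0,22,0
100,52,0,7,0
101,34,2,19,0
102,32,0,23,0
103,23,0,26,0
104,31,1,16,0
105,13,0,36,0
106,30,1,24,0
107,30,1,30,0
108,24,1,22,0
109,30,0,23,0
110,26,1,19,0
111,18,0,34,0
112,37,1,18,0
113,33,0,18,0
114,32,0,31,0
115,29,1,20,0
116,42,2,16,0
117,26,0,34,0
118,13,0,36,0
119,22,0,32,0
120,37,1,7,0
121,30,0,18,0
122,18,0,39,0
123,7,1,41,0
124,34,1,16,0
125,27,2,17,0
126,40,0,10,0
127,22,0,20,0
128,37,0,18,0
129,24,0,34,0
130,31,1,16,0
131,11,1,36,0
132,19,2,23,0
133,10,0,26,0
134,18,0,28,0
135,26,1,9,0
136,23,1,35,0
137,31,0,14,0
138,18,0,32,0
140,28,2,22,0
141,32,1,19,0
142,10,0,44,0
143,35,0,13,0
144,17,0,19,0
145,32,1,13,0
146,27,0,19,0
148,40,1,26,0
149,21,1,22,0
150,31,1,21,0
151,13,0,33,0
152,13,0,35,0
153,26,0,16,0
154,20,0,26,0
155,19,0,21,0
156,37,0,12,0
158,34,1,14,0
159,36,0,21,0
160,33,1,19,0
161,41,0,23,0
162,30,1,32,0
163,27,0,29,0
164,28,0,13,0
165,32,1,10,0
166,15,1,26,0
167,36,0,11,0
168,30,2,33,0
169,27,0,18,0
170,25,1,12,0
171,24,0,27,0
174,32,0,19,0
175,25,1,26,0
176,21,0,26,0
178,42,0,24,0
179,23,0,22,0
180,21,1,26,0
181,29,1,10,0
182,31,0,24,0
183,24,0,31,0
184,27,1,36,0
185,28,0,33,0
186,34,0,20,0
187,48,1,3,0
189,51,0,1,0
190,36,0,7,0
191,63,1,0,0
192,44,1,7,0
193,55,1,4,0
194,31,3,13,0
195,39,0,11,0
196,40,0,0,0
197,40,0,0,0
199,49,0,0,0
200,41,1,1,0
201,55,0,0,0
203,46,1,14,0
204,51,0,0,0
205,51,0,1,0
206,48,2,6,0
207,34,0,16,0
208,49,0,16,0
210,52,0,0,0
211,45,1,7,0
212,61,0,0,0
213,32,0,2,0
214,42,0,12,0
215,45,0,3,0
216,36,0,2,0
217,67,0,0,0
218,37,0,16,0
219,46,0,1,0
220,51,1,11,0
221,46,0,11,0
222,52,1,2,0
223,63,2,3,0
224,38,1,7,0
225,59,1,1,0
226,50,1,2,0
227,45,1,3,0
228,34,2,6,0
229,46,0,4,0
230,41,1,14,0
232,46,0,0,0
233,56,1,0,0
234,40,0,13,0
236,34,0,9,0
238,51,1,0,0
239,51,1,1,0
240,46,0,7,0
241,53,0,9,0
242,46,0,8,0
243,55,0,7,0
244,39,0,10,0
245,35,0,1,0
246,51,0,4,0
247,49,1,0,0
248,52,0,4,0
249,35,2,17,0
250,39,1,14,0
251,54,1,5,0
253,37,0,23,0
254,45,0,5,0
255,47,0,3,0
256,49,1,4,0
258,41,0,4,0
259,39,1,8,0
260,42,1,0,0
261,47,1,8,0
262,49,0,4,0
263,48,0,0,0
264,41,1,8,0
265,46,0,10,0
266,55,0,3,0
267,46,1,8,0
268,35,2,3,0
269,46,2,2,0
270,41,0,19,0
271,65,0,0,0
272,55,1,4,0
273,53,0,2,0
274,58,0,7,0
275,48,0,1,0
276,56,0,2,0
277,39,2,2,0
278,41,2,6,0
279,47,0,5,0
280,47,0,6,0
281,44,0,8,0
282,30,0,9,0
283,58,0,7,0
284,48,1,2,0
285,56,0,3,0
286,42,1,10,0
287,40,1,7,0
288,51,0,7,0
289,58,2,6,0
290,39,0,5,0
291,37,0,2,0
292,47,3,4,0
293,44,1,3,0
294,55,0,3,0
295,36,1,3,0
296,53,1,0,0
297,45,0,7,0
298,30,0,21,0
299,45,0,4,0
300,49,1,2,0
301,59,1,0,0
302,50,1,7,0
303,14,0,28,0
304,40,0,10,0
305,36,1,12,0
306,40,1,29,0
307,28,0,15,0
308,30,0,27,0
309,32,0,15,0
310,23,1,37,0
311,13,1,40,0
312,33,0,27,0
313,26,0,24,0
314,37,0,7,0
316,18,0,17,0
317,19,0,32,0
319,35,0,14,0
320,43,0,11,0
321,36,1,12,0
322,29,0,23,0
323,18,1,42,0
324,32,1,16,0
325,19,1,28,0
326,36,0,26,0
327,26,1,20,0
328,10,0,26,0
329,10,0,26,0
330,35,0,25,0
331,48,0,11,0
332,24,2,34,0
333,23,0,33,0
334,14,0,25,0
335,30,2,31,0
336,24,0,19,0
337,32,1,26,0
338,8,1,43,0
339,41,1,9,0
340,25,0,32,0
341,36,0,17,0
342,26,1,12,0
343,14,1,46,0
344,39,0,10,0
345,36,0,16,0
347,30,0,26,0
348,23,0,31,0
349,26,0,21,0
350,44,2,12,0
352,30,1,18,0
353,14,0,37,0
354,23,1,27,0
355,8,2,30,0
356,15,1,38,0
358,19,1,34,0
359,15,3,36,0
360,27,1,19,0
361,29,0,28,0
363,19,0,30,0
365,35,2,14,0
366,21,1,32,0
368,22,1,25,0
369,24,1,29,0
370,17,0,27,0
371,22,0,21,0
372,21,0,31,0
373,25,0,17,0
374,37,0,21,0
375,11,0,40,0
377,10,1,30,0
378,25,1,20,0
380,21,0,22,0
381,34,1,11,0
382,29,1,18,0
383,19,0,24,0
384,31,0,14,0
386,38,0,37,0
387,40,0,31,0
388,29,0,28,0
389,27,0,21,0
390,30,0,33,0
391,19,0,55,0
392,30,0,41,0
393,26,0,21,0
394,16,0,43,0
395,30,0,18,0
396,42,0,8,0
397,15,4,34,0
398,14,0,37,0
399,47,0,5,0
400,42,0,2,0
401,55,0,5,0
402,51,0,0,0
403,51,1,1,0
404,59,0,1,0
406,51,0,1,0
407,45,2,5,0
408,54,0,0,0
409,43,0,2,0
410,46,2,1,0
411,30,0,8,0
412,39,0,4,0
414,40,0,7,0
415,45,1,1,0
416,33,0,14,0
417,47,0,1,0
418,31,0,30,0
419,45,0,5,0
420,51,0,0,0
421,34,1,17,0
422,50,0,1,0
423,42,0,15,0
424,51,0,2,0
425,35,0,3,0
426,38,1,3,0
427,51,1,2,0
428,47,1,0,0
429,45,0,12,0
430,31,0,5,0
431,32,0,17,0
432,48,1,0,0
434,42,0,0,0
435,61,0,3,0
436,49,0,8,0
437,51,1,2,0
438,27,1,8,0
439,49,0,5,0
440,48,0,0,0
441,53,1,3,0
442,46,4,0,0
443,37,0,5,0
444,50,0,8,0
445,42,0,7,0
446,49,0,1,0
447,34,0,4,0
448,43,0,0,0
449,56,0,14,0
450,44,3,9,0
451,41,1,0,0
452,40,0,6,0
453,50,2,0,0
454,44,3,7,0
455,49,0,0,0
456,46,1,0,0
457,48,1,0,0
458,32,0,6,0
459,34,1,14,0
460,48,0,2,0
461,42,0,5,0
462,28,1,24,0
463,38,0,0,0
464,48,1,5,0
465,34,1,20,0
466,58,0,0,0
467,54,0,1,0
468,39,1,1,0
469,46,0,0,0
470,54,0,1,0
471,50,0,3,0
472,51,2,7,0
474,42,0,5,0
475,48,0,4,0
476,41,2,1,0
477,61,0,0,0
478,29,0,14,0
479,46,0,3,0
480,42,1,7,0
481,26,0,23,0
482,42,0,7,0
483,49,0,10,0
484,44,1,0,0
485,56,0,6,0
486,45,0,1,0
487,49,0,0,0
488,52,1,3,0
489,42,0,8,0
490,60,1,1,0
491,51,0,2,0
492,52,1,2,0
493,62,0,2,0
495,40,0,15,0
496,49,3,7,0
497,46,0,0,0
498,37,2,2,0
499,44,0,1,0
500,38,2,8,0
501,53,0,3,0
502,41,0,0,0
504,26,0,14,0
505,49,2,7,0
506,41,0,10,0
507,50,1,0,0
508,59,1,3,0
510,47,0,1,0
511,47,0,11,0
512,46,0,10,0
513,53,0,1,0
514,43,0,1,0
515,43,1,1,0
517,49,1,1,0
518,37,1,8,0
519,41,1,12,0
520,41,0,11,0
521,37,1,3,0
522,43,1,1,0
523,43,0,0,0
524,43,0,9,0
525,44,0,6,0
526,49,0,4,0
527,48,1,0,0
528,33,0,11,0
530,45,0,1,0
531,56,0,1,0
532,45,2,1,0
533,38,0,9,0
534,29,1,15,0
535,45,0,8,0
536,46,1,0,0
537,46,0,6,0
538,55,1,6,0
539,42,0,2,0
540,42,0,5,0
541,40,0,0,0
542,37,1,9,0
543,35,1,12,0
544,42,1,2,0
545,38,0,8,0
546,54,0,1,0
547,29,1,6,0
548,39,0,0,0
549,61,0,0,0
550,43,0,5,0
551,42,0,2,0
553,48,1,0,0
554,43,1,6,0
555,42,0,5,0
556,36,0,18,0
558,49,0,5,0
559,39,1,4,0
560,43,0,0,0
561,43,0,9,0
562,46,2,1,0
563,52,1,0,0
564,32,2,2,0
565,39,1,0,0
566,58,2,4,0
567,40,0,5,0
568,52,0,1,0
569,50,0,7,0
570,39,0,11,0
572,45,0,2,0
573,52,1,3,0
574,35,0,0,0
575,60,1,3,0
576,60,1,0,0
577,36,0,13,0
578,36,0,11,0
580,48,0,1,0
581,48,0,14,0
582,42,0,0,0
583,48,0,2,0
584,37,1,17,0
585,40,1,5,0
586,39,0,4,0
587,43,0,2,0
588,51,0,1,0
589,34,0,2,0
590,40,0,9,0
591,30,0,10,0
593,54,1,5,0
595,39,0,7,0
596,47,0,4,0
597,54,0,2,0
598,44,0,1,0
599,45,0,0,0
600,40,0,0,0
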