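pos,c,noc,mc,hmc
1,63,0,6,0
2,45,0,5,0
3,38,0,8,0
4,40,0,16,0
5,54,0,5,0
6,47,1,5,0
7,42,0,11,0
8,50,1,5,0
9,45,2,4,0
10,49,0,1,0
11,58,0,3,0
12,38,1,7,0
13,55,1,4,0
14,47,0,5,0
15,36,0,5,0
16,40,0,0,0
17,49,1,0,0
18,46,1,2,0
19,36,0,7,0
20,46,2,0,0
21,43,0,0,0
22,46,0,3,0
23,39,0,21,0
24,38,0,2,0
26,53,0,2,0
27,41,1,0,0
28,40,0,6,0
29,42,0,0,0
30,46,0,4,0
31,31,0,11,0
32,41,0,4,0
33,45,0,4,0
34,58,0,4,0
35,42,2,6,0
36,59,0,0,0
37,56,0,4,0
38,57,0,1,0
39,33,2,7,0
40,52,0,7,0
42,23,2,9,0
43,46,0,2,0
44,36,0,10,0
46,52,0,0,0
48,47,0,4,0
49,44,1,3,0
50,49,2,6,0
51,53,0,1,0
52,35,2,5,0
54,63,1,0,0
55,39,0,5,0
56,51,1,0,0
57,46,0,2,0
58,36,2,2,0
59,43,1,16,0
60,45,0,0,0
61,51,0,3,0
62,39,0,6,0
63,42,0,4,0
64,47,0,7,0
65,45,1,4,0
66,47,2,0,0
67,31,1,9,0
68,59,2,3,0
69,25,0,19,0
70,40,1,13,0
71,46,0,19,0
72,50,0,2,0
73,44,0,8,0
74,42,2,0,0
75,55,0,4,0
77,36,0,2,0
79,47,0,9,0
81,47,0,1,0
83,52,0,2,0
84,55,2,3,0
86,55,0,0,0
87,48,1,5,0
88,50,0,0,0
89,45,0,1,0
90,38,0,25,0
91,51,0,6,0
92,37,0,17,0
93,40,0,5,0
94,49,0,6,0
95,56,0,2,0
96,55,0,0,0
97,47,0,0,0
98,63,0,5,0
99,43,1,0,0
100,46,0,9,0
101,54,1,1,0
102,49,0,2,0
103,38,0,3,0
104,42,1,7,0
105,51,0,0,0
106,46,0,6,0
107,46,0,5,0
108,48,1,2,0
109,43,0,3,0
110,40,0,2,0
111,44,0,4,0
112,42,1,13,0
113,52,0,0,0
114,59,0,0,0
115,46,0,6,0
116,47,1,1,0
117,47,0,0,0
118,50,0,6,0
119,47,0,3,0
120,61,2,0,0
121,55,0,0,0
122,63,1,0,0
123,61,0,1,0
124,45,0,3,0
125,38,0,4,0
126,51,1,9,0
127,40,1,1,0
128,46,2,0,0
129,42,0,7,0
130,39,1,16,0
131,42,0,2,0
132,59,1,1,0
133,51,1,9,0
134,50,0,0,0
135,38,3,7,0
136,61,0,0,0
137,57,1,1,0
138,65,0,0,0
140,51,1,11,0
141,47,0,9,0
142,47,0,0,0
143,45,1,2,0
144,44,0,9,0
145,50,0,5,0
146,41,0,13,0
148,52,0,8,0
149,46,0,4,0
150,58,1,6,0
151,48,0,4,0
152,53,1,6,0
153,47,0,0,0
154,46,1,0,0
155,39,0,0,0
156,49,0,4,0
158,50,0,6,0
159,31,2,15,0
160,42,3,5,0
161,49,0,0,0
162,62,0,4,0
163,46,1,12,0
164,36,1,6,0
165,34,0,16,0
166,51,3,3,0
167,44,1,12,0
168,37,1,7,0
169,39,1,3,0
170,45,0,2,0
171,39,0,14,0
174,42,0,1,0
175,41,2,1,0
176,34,0,8,0
178,48,0,7,0
179,39,0,6,0
180,45,0,0,0
181,29,0,15,0
182,41,1,5,0
183,39,0,1,0
184,39,0,3,0
185,41,1,4,0
186,27,0,22,0
187,54,0,3,0
189,36,0,2,0
190,32,0,3,0
191,43,1,2,0
192,52,1,5,0
193,51,0,0,0
194,55,1,0,0
195,52,1,0,0
196,35,0,11,0
197,37,1,18,0
199,40,0,4,0
200,37,3,3,0
201,46,0,1,0
203,50,0,0,0
204,54,1,4,0
205,34,0,4,0
206,47,0,5,0
207,56,0,1,0
208,43,0,1,0
210,34,0,6,0
211,46,0,2,0
212,37,1,8,0
213,41,0,1,0
214,34,0,15,0
215,47,0,1,0
216,42,0,4,0
217,44,1,5,0
218,30,1,16,0
219,41,0,8,0
220,44,1,1,0
221,46,0,0,0
222,52,0,4,0
223,44,1,5,0
224,43,0,2,0
225,42,1,5,0
226,41,0,1,0
227,44,1,6,0
228,48,0,2,0
229,45,0,4,0
230,41,0,3,0
232,50,0,4,0
233,36,0,3,0
234,26,0,10,0
236,59,2,0,0
238,41,0,11,0
239,44,1,5,0
240,58,0,7,0
241,54,1,4,0
242,50,0,7,0
243,43,0,11,0
244,56,1,9,0
245,48,0,12,0
246,47,1,5,0
247,33,1,15,0
248,49,0,3,0
249,33,0,3,0
250,53,1,0,0
251,36,0,10,0
253,52,0,1,0
254,41,1,9,0
255,47,0,2,0
256,54,0,3,0
258,49,1,0,0
259,34,0,13,0
260,63,0,1,0
261,40,0,1,0
262,52,0,3,0
263,39,0,16,0
264,49,0,2,0
265,50,0,2,0
266,46,0,8,0
267,54,2,0,0
268,33,0,6,0
269,49,1,3,0
270,46,1,6,0
271,46,1,6,0
272,45,1,14,0
273,55,2,2,0
274,47,0,0,0
275,46,0,2,0
276,46,0,9,0
277,49,0,0,0
278,29,0,4,0
279,54,0,2,0
280,56,0,4,0
281,65,1,3,0
282,45,1,0,0
283,48,2,0,0
284,39,1,6,0
285,52,0,2,0
286,38,2,4,0
287,45,5,1,0
288,50,1,2,0
289,45,3,0,0
290,48,0,7,0
291,53,0,0,0
292,46,0,0,0
293,34,0,19,0
294,55,0,0,0
295,35,0,15,0
296,34,0,18,0
297,42,0,6,0
298,36,0,14,0
299,47,0,9,0
300,31,0,5,0
301,55,2,5,0
302,38,0,9,0
303,44,1,3,0
304,44,0,13,0
305,46,1,8,0
306,39,0,11,0
307,45,0,7,0
308,52,1,4,0
309,37,0,3,0
310,44,1,1,0
311,49,1,9,0
312,65,0,0,0
313,48,1,0,0
314,35,0,9,0
316,34,1,6,0
317,39,0,6,0
319,52,0,11,0
320,35,3,20,0
321,45,0,1,0
322,49,0,4,0
323,44,0,0,0
324,40,0,8,0
325,44,0,11,0
326,42,0,4,0
327,51,0,0,0
328,50,0,2,0
329,42,0,3,0
330,47,1,0,0
331,48,1,0,0
332,49,1,2,0
333,43,2,2,0
334,41,0,0,0
335,45,1,4,0
336,57,1,0,0
337,50,2,4,0
338,54,0,5,0
339,58,0,6,0
340,32,1,9,0
341,30,0,2,0
342,42,0,11,0
343,43,2,5,0
344,37,1,1,0
345,47,0,0,0
347,61,0,0,0
348,44,0,0,0
349,47,0,0,0
350,46,0,6,0
352,39,0,5,0
353,40,1,7,0
354,57,0,2,0
355,35,1,13,0
356,38,0,15,0
358,48,0,8,0
359,52,2,0,0
360,37,0,2,0
361,48,0,4,0
363,54,3,2,0
365,53,0,0,0
366,37,0,13,0
368,49,1,4,0
369,48,0,1,0
370,29,1,26,0
371,37,0,9,0
372,45,0,5,0
373,42,0,0,0
374,47,0,4,0
375,47,0,8,0
377,36,0,13,0
378,60,0,7,0
380,48,0,2,0
381,61,1,5,0
382,51,0,0,0
383,39,0,1,0
384,45,0,11,0
386,46,2,5,0
387,38,0,0,0
388,40,1,6,0
389,47,0,3,0
390,46,0,2,0
391,37,1,9,0
392,41,0,13,0
393,45,1,9,0
394,44,0,2,0
395,52,0,0,0
396,49,0,1,0
397,57,0,0,0
398,51,0,1,0
399,34,0,6,0
400,50,0,2,0
401,39,0,0,0
402,43,1,0,0
403,53,0,0,0
404,56,0,1,0
406,53,0,2,0
407,45,0,1,0
408,55,1,1,0
409,51,0,2,0
410,44,1,6,0
411,59,1,3,0
412,43,0,16,0
414,49,0,4,0
415,42,0,1,0
416,48,0,0,0
417,38,0,0,0
418,52,0,2,0
419,67,1,1,0
420,37,0,6,0
421,44,0,2,0
422,44,0,1,0
423,50,0,1,0
424,47,1,1,0
425,49,1,0,0
426,35,2,15,0
427,42,0,7,0
428,54,0,0,0
429,49,0,4,0
430,50,0,0,0
431,47,0,5,0
432,49,1,0,0
434,48,0,1,0
435,63,0,2,0
436,40,1,10,0
437,33,0,5,0
438,43,0,13,0
439,43,2,0,0
440,41,1,5,0
441,46,0,3,0
442,48,0,1,0
443,52,1,2,0
444,40,0,3,0
445,46,1,3,0
446,45,1,10,0
447,44,0,2,0
448,33,1,15,0
449,47,1,1,0
450,40,1,0,0
451,50,1,4,0
452,51,0,6,0
453,54,1,2,0
454,59,0,6,0
455,49,0,4,0
456,47,0,0,0
457,58,0,1,0
458,53,2,1,0
459,46,0,12,0
460,48,1,3,0
461,39,0,0,0
462,39,0,1,0
463,58,0,3,0
464,47,0,4,0
465,42,1,2,0
466,47,2,2,0
467,29,0,12,0
468,39,0,10,0
469,51,0,0,0
470,54,1,1,0
471,42,0,5,0
472,64,0,1,0
474,33,0,14,0
475,47,0,1,0
476,41,0,2,0
477,52,0,0,0
478,45,1,5,0
479,15,1,28,0
480,45,1,7,0
481,56,1,4,0
482,43,0,3,0
483,44,3,4,0
484,28,0,20,0
485,30,0,26,0
486,64,0,5,0
487,43,2,10,0
488,47,0,0,0
489,48,1,6,0
490,43,0,2,0
491,58,0,12,0
492,37,2,6,0
493,38,0,7,0
495,44,1,4,0
496,47,0,0,0
497,38,0,7,0
498,55,1,2,0
499,43,1,1,0
500,39,1,2,0
501,57,0,4,0
502,34,0,19,0
504,48,2,4,0
505,25,0,26,0
506,57,1,2,0
507,38,0,0,0
508,51,1,2,0
510,48,0,4,0
511,23,0,10,0
512,46,2,3,0
513,42,0,11,0
514,40,0,3,0
515,35,0,1,0
517,49,0,1,0
518,42,1,7,0
519,55,0,1,0
520,20,0,25,0
521,45,1,7,0
522,54,0,3,0
523,52,0,0,0
524,35,0,11,0
525,52,0,0,0
526,38,0,1,0
527,47,0,0,0
528,39,1,6,0
530,47,2,0,0
531,32,2,17,0
532,34,1,10,0
533,45,0,7,0
534,45,1,9,0
535,46,1,3,0
536,33,1,3,0
537,43,0,12,0
538,53,1,7,0
539,50,1,0,0
540,21,1,21,0
541,41,1,14,0
542,42,0,3,0
543,21,2,18,0
544,51,0,5,0
545,54,0,4,0
546,36,1,4,0
547,37,0,1,0
548,59,0,1,0
549,29,0,11,0
550,50,0,12,0
551,68,0,1,0
553,40,1,2,0
554,36,1,7,0
555,55,0,0,0
556,51,0,0,0
558,51,0,14,0
559,41,0,2,0
560,47,1,5,0
561,41,1,3,0
562,43,1,6,0
563,39,0,1,0
564,41,1,4,0
565,58,0,1,0
566,43,1,4,0
567,56,1,0,0
568,20,0,10,0
569,31,0,4,0
570,35,1,6,0
572,49,0,0,0
573,44,0,11,0
574,45,1,8,0
575,47,0,2,0
576,28,1,16,0
577,24,0,16,0
578,26,1,9,0
580,27,0,28,0
581,38,0,1,0
582,57,0,7,0
583,43,1,0,0
584,52,0,7,0
585,39,1,3,0
586,46,0,6,0
587,35,0,5,0
588,51,0,0,0
589,51,0,1,0
590,46,0,1,0
591,35,1,13,0
593,43,0,0,0
595,51,1,1,0
596,37,0,1,0
597,44,0,11,0
598,48,0,0,0
599,44,0,0,0
600,46,1,5,0
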